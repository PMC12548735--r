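test_that("alignment cleaning implements the three rules and boundaries", {
  ## 5-column insertion present in 1 of 10 rows
  core <- strrep("A", 10)
  rows <- c(paste0("MKVLA", "WWWWW", core),
            replicate(9, paste0("MKVLA", "-----", core)))
  names(rows) <- sprintf("s%02d", 1:10)
  cleaned <- clean_alignment(msa_matrix(rows), min_len = 10)
  expect_equal(ncol(cleaned), 15)
  expect_equal(length(attr(cleaned, "removed_columns")), 5)

  ## terminal column with 1/20 coverage is cropped
  rows <- c(paste0("M", strrep("K", 60)),
            replicate(19, paste0("-", strrep("K", 60))))
  names(rows) <- sprintf("s%02d", 1:20)
  cleaned <- clean_alignment(msa_matrix(rows), min_len = 10)
  expect_equal(ncol(cleaned), 60)

  ## row with 49 residues dropped, 50 retained
  rows <- c(a = strrep("K", 60), b = strrep("K", 60),
            c = paste0(strrep("K", 49), strrep("-", 11)),
            d = paste0(strrep("K", 50), strrep("-", 10)))
  cleaned <- clean_alignment(msa_matrix(rows))
  expect_setequal(rownames(cleaned), c("a", "b", "d"))
  expect_equal(attr(cleaned, "removed_rows"), "c")

  expect_error(clean_alignment(msa_matrix(c(a = strrep("K", 10),
                                            b = strrep("K", 10)))),
               "removed all rows")
})

test_that("p-distances match direct recounting", {
  m <- msa_matrix(c(a = "AAAA", b = "AAAT", c = "AAAA"))
  d <- p_distance_matrix(m, min_shared = 2)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)

  set.seed(61)
  rows <- vapply(1:5, function(i) {
    paste0(sample(c("A", "C", "G", "T", "-"), 30, replace = TRUE),
           collapse = "")
  }, "")
  names(rows) <- paste0("r", 1:5)
  m <- msa_matrix(rows)
  d <- p_distance_matrix(m, min_shared = 1)
  for (i in 1:4) for (j in (i + 1):5) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(d[i, j], sum(m[i, both] != m[j, both]) / sum(both))
  }

  ## sparse pair flagged at max + 0.1
  m2 <- msa_matrix(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT",
                     c = "A---------"))
  d2 <- p_distance_matrix(m2, min_shared = 5)
  expect_equal(d2["a", "c"], max(0.1) + 0.1)
  expect_false(is.null(attr(d2, "flagged_pairs")))
})

test_that("NJ recovers additive trees exactly and handles n = 3", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  D <- ape::cophenetic.phylo(tree)
  est <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  ## 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  est3 <- nj_tree(D3)
  C3 <- ape::cophenetic.phylo(est3)
  expect_equal(C3[c("A", "B", "C"), c("A", "B", "C")], D3, tolerance = 1e-9)

  Dn <- D3; Dn[1, 2] <- Dn[2, 1] <- NaN
  expect_error(nj_tree(Dn), "NaN")
})

test_that("NJ topology matches exhaustive least-squares on 6 taxa", {
  set.seed(62)
  ## ultrametric tree -> clean additive distances
  tree <- ape::compute.brlen(ape::rtree(6), method = "Grafen")
  D <- ape::cophenetic.phylo(tree)
  est <- nj_tree(D)

  tips <- rownames(D)
  pairs <- t(combn(tips, 2))
  rss_for <- function(top) {
    n_tip <- length(top$tip.label)
    A <- matrix(0, nrow(pairs), nrow(top$edge))
    for (e in seq_len(nrow(top$edge))) {
      child <- top$edge[e, 2]
      below <- if (child <= n_tip) top$tip.label[child]
      else top$tip.label[phangorn::Descendants(top, child, "tips")[[1]]]
      onpath <- xor(pairs[, 1] %in% below, pairs[, 2] %in% below)
      A[onpath, e] <- 1
    }
    y <- D[pairs]
    fit <- lm.fit(A, y)
    sum(fit$residuals^2)
  }
  all_tops <- phangorn::allTrees(6, rooted = FALSE, tip.label = tips)
  expect_length(all_tops, 105)
  rss <- vapply(all_tops, rss_for, 0)
  best <- all_tops[[which.min(rss)]]
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(est), best)), 0)
})

test_that("NJ consistency on random additive matrices up to 12 taxa", {
  set.seed(63)
  for (n in c(5, 8, 12)) {
    for (rep in 1:10) {
      case <- random_additive_case(n)
      est <- nj_tree(case$D)
      expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(est),
                                                ape::unroot(case$tree))), 0)
      expect_equal(ape::cophenetic.phylo(est)[rownames(case$D),
                                              colnames(case$D)],
                   case$D, tolerance = 1e-9)
    }
  }
})

test_that("bootstrap supports behave as advertised", {
  ## two well-separated clusters: high-SNR alignment
  set.seed(64)
  left <- strsplit(random_protein(80), "")[[1]]
  right <- strsplit(random_protein(80), "")[[1]]
  mutate <- function(x, rate = 0.05) {
    mut <- runif(length(x)) < rate
    x[mut] <- sample(rdrpscreen:::AA20, sum(mut), replace = TRUE)
    paste0(x, collapse = "")
  }
  rows <- c(L1 = mutate(left), L2 = mutate(left),
            R1 = mutate(right), R2 = mutate(right))
  msa <- msa_matrix(rows)
  tr <- bootstrap_supports(msa, n_reps = 50, seed = 5)
  ## the (L1,L2)|(R1,R2) split is the single internal edge
  internal <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(internal, na.rm = TRUE), 0.95)

  tr1 <- bootstrap_supports(msa, n_reps = 1, seed = 9)
  expect_true(all(suppressWarnings(as.numeric(tr1$node.label)) %in%
                    c(0, 1, NA)))
  tr2a <- bootstrap_supports(msa, n_reps = 20, seed = 11)
  tr2b <- bootstrap_supports(msa, n_reps = 20, seed = 11)
  expect_identical(tr2a$node.label, tr2b$node.label)
})

test_that("patristic distances equal graph shortest paths", {
  tree <- ape::read.tree(text = "(A:0.1,(B:0.2,C:0.3):0.1);")
  expect_equal(patristic_distance(tree, "A", "B"), 0.4)
  expect_equal(patristic_distance(tree, "B", "B"), 0)
  expect_error(patristic_distance(tree, "A", "Z"), "unknown leaf")

  set.seed(65)
  tr <- ape::rtree(10)
  n_nodes <- 10 + tr$Nnode
  W <- matrix(Inf, n_nodes, n_nodes); diag(W) <- 0
  for (e in seq_len(nrow(tr$edge))) {
    i <- tr$edge[e, 1]; j <- tr$edge[e, 2]
    W[i, j] <- W[j, i] <- tr$edge.length[e]
  }
  for (k in seq_len(n_nodes)) for (i in seq_len(n_nodes)) {
    W[i, ] <- pmin(W[i, ], W[i, k] + W[k, ])
  }
  for (a in 1:9) for (b in (a + 1):10) {
    expect_equal(patristic_distance(tr, tr$tip.label[a], tr$tip.label[b]),
                 W[a, b], tolerance = 1e-9)
  }
})

test_that("OTU assignment takes the nearest known with deterministic ties", {
  tree <- ape::read.tree(text = "((q:0.2,K1:0.2):0.1,(K2:0.5,x:0.5):0.6);")
  otu_map <- c(K1 = "OTU-A", K2 = "OTU-B")
  res <- assign_otu(tree, "q", c("K1", "K2"), otu_map)
  expect_equal(res$otu, "OTU-A")
  expect_equal(res$patristic_distance, 0.4)

  ## equidistant knowns -> lexicographically smallest, logged
  tie_tree <- ape::read.tree(text = "(q:0.1,KB:0.3,KA:0.3);")
  withr::local_options(rdrpscreen.verbose = TRUE)
  expect_message(
    res <- assign_otu(tie_tree, "q", c("KB", "KA"),
                      c(KA = "OTU-1", KB = "OTU-2")), "tie")
  expect_equal(res$nearest_known_id, "KA")

  expect_error(assign_otu(tree, "K1", c("K1", "K2"), otu_map), "also listed")
})

test_that("a distance of exactly 1.5 fails the branch-length criterion", {
  tree <- ape::read.tree(text = "(q:0.75,K1:0.75,K2:3);")
  res <- assign_otu(tree, "q", c("K1", "K2"), c(K1 = "O1", K2 = "O2"))
  expect_equal(res$patristic_distance, 1.5)
  call <- integrate_evidence(bundle(tree = res$patristic_distance, hmmer = 1))
  expect_false(call$crit_tree)
})

test_that("family assignment requires supported single-family clades", {
  tr <- ape::read.tree(text = "((q:1,(k1:1,k2:1)0.95:1)0.9:1,k3:1);")
  fam <- c(k1 = "FamA", k2 = "FamA", k3 = "FamB")
  expect_equal(assign_family_by_clade(tr, "q", fam)$family, "FamA")

  tr07 <- ape::read.tree(text = "((q:1,(k1:1,k2:1)0.95:1)0.7:1,k3:1);")
  expect_true(is.na(assign_family_by_clade(tr07, "q", fam)$family))

  ## support exactly 0.8 passes (inclusive)
  tr08 <- ape::read.tree(text = "((q:1,(k1:1,k2:1)0.95:1)0.8:1,k3:1);")
  expect_equal(assign_family_by_clade(tr08, "q", fam)$family, "FamA")

  ## mixed-family clades never assign
  fam_mixed <- c(k1 = "FamA", k2 = "FamB", k3 = "FamB")
  expect_true(is.na(assign_family_by_clade(tr, "q", fam_mixed)$family))
})

test_that("every family assignment is backed by a supported pure clade", {
  set.seed(66)
  for (rep in 1:15) {
    tr <- ape::rtree(6)
    tr$node.label <- round(runif(tr$Nnode), 2)
    knowns <- sample(tr$tip.label, 4)
    q <- setdiff(tr$tip.label, knowns)[1]
    fam <- setNames(sample(c("F1", "F2"), 4, replace = TRUE), knowns)
    res <- assign_family_by_clade(tr, q, fam)
    clades <- rdrpscreen:::.clade_tips(tr)
    sup <- as.numeric(tr$node.label)
    ok <- vapply(seq_along(clades), function(k) {
      tips <- clades[[k]]
      kn <- intersect(tips, knowns)
      q %in% tips && !is.na(sup[k]) && sup[k] >= 0.8 && length(kn) > 0 &&
        length(unique(fam[kn])) == 1
    }, TRUE)
    if (is.na(res$family)) {
      expect_false(any(ok))
    } else {
      expect_true(any(ok))
    }
  }
})

test_that("tree congruence is 0 for identical, 1 for conflicting quartets", {
  a <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  b <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(tree_congruence(a, a), 0)
  expect_equal(tree_congruence(a, b), 1)
  expect_error(tree_congruence(ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);"),
                               ape::read.tree(text = "((A:1,B:1):1,(C:1,F:1):1);")),
               "4 shared leaves")

  set.seed(67)
  for (rep in 1:10) {
    ta <- ape::rtree(6); tb <- ape::rtree(6)
    tb$tip.label <- sample(ta$tip.label)
    got <- tree_congruence(ta, tb)
    pa <- oracle_bipartitions(ta); pb <- oracle_bipartitions(tb)
    rf <- length(setdiff(pa, pb)) + length(setdiff(pb, pa))
    expect_equal(got, rf / (2 * (6 - 3)))
  }
})

test_that("co-diverging trees beat leaf-permuted controls", {
  set.seed(68)
  wins <- 0L; n_seeds <- 20L
  for (rep in seq_len(n_seeds)) {
    host <- ape::rtree(8, br = function(k) runif(k, 0.1, 0.5))
    sim <- phangorn::simSeq(host, l = 400, type = "AA")
    m <- toupper(as.character(sim))
    est <- nj_tree(p_distance_matrix(m))
    perm <- est
    perm$tip.label <- sample(perm$tip.label)
    same <- tree_congruence(host, est)
    ctrl <- tree_congruence(host, perm)
    if (same <= ctrl) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})
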