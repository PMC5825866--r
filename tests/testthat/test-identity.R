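test_that("binary dissimilarity matches its definition and enumeration oracle", {
  expect_equal(binary_dissimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 2 / 3)
  expect_equal(binary_dissimilarity(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(binary_dissimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_error(binary_dissimilarity(c(0, 0), c(0, 0)),
               class = "microlens_undefined_distance_error")

  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    repeat {
      x <- rbinom(n, 1, 0.4); y <- rbinom(n, 1, 0.4)
      if (sum(x) + sum(y) > 0) break
    }
    expect_equal(binary_dissimilarity(x, y), oracle_binary(x, y))
  }
})

test_that("the pairwise dissimilarity matrix agrees with the scalar operation", {
  set.seed(12)
  bits <- tibble::tibble(gene = sprintf("g%02d", 1:30))
  for (s in c("s1", "s2", "s3", "s4")) bits[[s]] <- rbinom(30, 1, 0.5)
  d <- as.matrix(dissimilarity_matrix(bits))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  samples <- c("s1", "s2", "s3", "s4")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j],
                 binary_dissimilarity(bits[[samples[i]]], bits[[samples[j]]]))
  }

  # identical columns are at distance zero
  bits$s5 <- bits$s1
  d5 <- as.matrix(dissimilarity_matrix(bits))
  expect_equal(d5["s1", "s5"], 0)

  # restriction to retained genes can make a pair undefined
  bits2 <- tibble::tibble(gene = c("a", "b"), s1 = c(1L, 0L), s2 = c(1L, 0L))
  expect_error(dissimilarity_matrix(bits2, retained_genes = "b"),
               class = "microlens_undefined_distance_error")
})

test_that("principal coordinates reproduce hand-worked configurations", {
  # three collinear points at unit spacing: one positive eigenvalue 2,
  # 1-D coordinates {-1, 0, 1} up to sign
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa(d)
  expect_equal(ord$eig[1], 2, tolerance = 1e-10)
  expect_equal(ncol(ord$points), 1)
  expect_equal(sort(ord$points[, 1]), c(-1, 0, 1), tolerance = 1e-8,
               ignore_attr = TRUE)

  # unit equilateral triangle: two equal positive eigenvalues 1/2
  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoa(d3)
  expect_equal(ord3$eig[1:2], c(0.5, 0.5), tolerance = 1e-10)

  # coincident points: no positive signal, all coordinates zero
  d0 <- matrix(0, 4, 4)
  ord0 <- pcoa(d0)
  expect_true(all(abs(ord0$eig) < 1e-10))
  expect_equal(ncol(ord0$points), 0)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "microlens_validation_error")
  expect_error(pcoa(matrix(c(0, -1, -1, 0), 2, 2)),
               class = "microlens_validation_error")
})

test_that("principal coordinates agree with classical scaling and round-trip distances", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    pts <- matrix(runif(2 * n, -3, 3), n, 2)
    rownames(pts) <- paste0("p", seq_len(n))
    d <- dist(pts)
    ord <- pcoa(d)
    # distances reconstructed from positive-eigenvalue coordinates
    expect_equal(as.numeric(dist(ord$points)), as.numeric(d), tolerance = 1e-8)
    # eigenvalues match base classical scaling
    cs <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
    expect_equal(ord$eig[1:2], cs$eig[1:2], tolerance = 1e-8)
  }
})

test_that("proximity ranking orders tissues like a brute-force distance sort", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    pts <- matrix(rnorm(2 * n), n, 2,
                  dimnames = list(c("query", paste0("t", seq_len(n - 1))), NULL))
    ord <- pcoa(dist(pts))
    ranked <- rank_by_proximity(ord, "query")
    brute <- sqrt(colSums((t(pts[-1, , drop = FALSE]) - pts[1, ])^2))
    brute_order <- names(sort(brute))
    # distances must agree; order may differ only under exact ties
    expect_equal(ranked$distance,
                 unname(brute[ranked$tissue]), tolerance = 1e-8)
    expect_equal(ranked$tissue, brute_order)
  }

  # coincident query: that tissue first at distance zero; 1-D hand case
  pts <- matrix(c(0, 1, -2), 3, 1, dimnames = list(c("query", "near", "far"), NULL))
  ord <- pcoa(dist(pts))
  ranked <- rank_by_proximity(ord, "query")
  expect_equal(ranked$tissue, c("near", "far"))
  expect_error(rank_by_proximity(ord, "absent"),
               class = "microlens_lookup_error")
})

test_that("a noiseless query inherits exactly its tissue's marker set", {
  sim <- flat_sim(n_tissues = 10, n_genes = 1000, markers_per_tissue = 50)
  comp <- build_marker_sets(sim$truth, top_m = 50, spec_frac = 0.1)
  q <- sim$truth[c("gene", "tissue03")]
  expect_setequal(query_marker_set(q, comp), sim$markers$tissue03)

  # spec_frac = 0 with every gene in at least one top list: empty marker set
  comp0 <- build_marker_sets(sim$truth, top_m = 500, spec_frac = 0)
  top <- query_marker_set(q, comp0)
  expect_length(top, 0)

  # unharmonised universe is rejected
  q_bad <- q[-1, ]
  expect_error(query_marker_set(q_bad, comp),
               class = "microlens_incompatibility_error")
})

test_that("one-sided Fisher p matches the hypergeometric tail oracle", {
  expect_equal(fisher_enrichment_p(5, 0, 0, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(fisher_enrichment_p(2, 0, 1, 7), 1 / 15, tolerance = 1e-12)
  # disjoint sets in a large universe: least extreme outcome, p = 1
  expect_equal(fisher_enrichment_p(0, 5, 5, 90), 1)

  set.seed(61)
  for (i in 1:200) {
    n_univ <- sample(4:30, 1)
    k <- sample.int(n_univ, 1)
    n <- sample.int(n_univ, 1)
    lo <- max(0, k + n - n_univ)
    a <- lo + sample.int(min(k, n) - lo + 1, 1) - 1
    expect_equal(fisher_enrichment_p(a, n - a, k - a, n_univ - k - n + a),
                 oracle_fisher_p(a, n - a, k - a, n_univ - k - n + a),
                 tolerance = 1e-12)
  }
})

test_that("the enrichment table has coherent counts, BH values and ranking", {
  sim <- flat_sim(n_tissues = 10, n_genes = 1000, markers_per_tissue = 50)
  comp <- build_marker_sets(sim$truth, top_m = 50, spec_frac = 0.1)
  enr <- fisher_enrichment(sim$markers$tissue07, comp)
  expect_equal(enr$tissue[1], "tissue07")
  expect_true(all(enr$a + enr$b + enr$c + enr$d == length(comp$gene_universe)))
  expect_true(all(enr$p_value >= 0 & enr$p_value <= 1))
  expect_true(all(enr$fdr >= 0 & enr$fdr <= 1))
  expect_equal(enr$fdr, bh_adjust(enr$p_value), tolerance = 1e-12)
  expect_equal(enr$rank, seq_len(nrow(enr)))
  # sorted by p, the FDR column is non-decreasing
  expect_true(all(diff(enr$fdr[order(enr$p_value)]) >= -1e-15))

  expect_error(fisher_enrichment(character(0), comp),
               class = "microlens_degenerate_input_error")
  expect_error(fisher_enrichment("not_a_gene", comp),
               class = "microlens_incompatibility_error")
})

test_that("BH adjustment equals the brute-force step-up on random inputs", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03)), c(0.015, 0.015, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)

  set.seed(71)
  for (i in 1:100) {
    m <- sample(1:50, 1)
    p <- runif(m)
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(got >= p / m - 1e-15 & got <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "microlens_validation_error")
})

test_that("replicate correlation behaves at its analytic anchors", {
  x <- tibble::tibble(gene = c("a", "b", "c"), r1 = c(1, 2, 3), r2 = c(1, 2, 3),
                      r3 = c(2, 4, 6), r4 = c(3, 2, 1), flat = c(2, 2, 2))
  expect_equal(replicate_correlation(x, "r1", "r2"), 1.0)
  expect_equal(replicate_correlation(x, "r1", "r3", log_transform = FALSE), 1.0)
  expect_equal(replicate_correlation(x, "r1", "r4", log_transform = FALSE), -1.0)
  expect_error(replicate_correlation(x, "r1", "flat"),
               class = "microlens_undefined_correlation_error")
  expect_error(replicate_correlation(x, "r1", "missing"),
               class = "microlens_lookup_error")
})

test_that("relabelling tissues permutes identity results identically", {
  sim <- simulate_compendium(n_tissues = 6, n_genes = 600,
                             markers_per_tissue = 20, seed = 13)
  q <- simulate_query(sim, "tissue04", seed = 14)
  res <- score_identity(sim$expression, q, k = 100, top_m = 200, spec_frac = 1 / 6)

  tissues <- names(sim$expression)[-1]
  relabel <- setNames(paste0("x_", rev(tissues)), tissues)
  shuffled <- sim$expression
  names(shuffled)[-1] <- unname(relabel[names(shuffled)[-1]])
  res2 <- score_identity(shuffled, q, k = 100, top_m = 200, spec_frac = 1 / 6)

  e1 <- res$enrichment
  e2 <- res2$enrichment
  e2$tissue <- names(relabel)[match(e2$tissue, relabel)]
  expect_equal(dplyr::arrange(as_tibble(e1)[c("tissue", "a", "p_value")], tissue),
               dplyr::arrange(as_tibble(e2)[c("tissue", "a", "p_value")], tissue))
  p1 <- res$proximity
  p2 <- res2$proximity
  p2$tissue <- names(relabel)[match(p2$tissue, relabel)]
  expect_equal(dplyr::arrange(p1[c("tissue", "distance")], tissue),
               dplyr::arrange(p2[c("tissue", "distance")], tissue))
})
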