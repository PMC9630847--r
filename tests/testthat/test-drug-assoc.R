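planted_screen_data <- function(seed, n = 300, effect = c(-1, 1),
                                noise = 0.3) {
  set.seed(seed)
  samples <- paste0("s", 1:n)
  g1 <- rnorm(n)
  g2 <- rnorm(n)
  g3 <- rnorm(n)
  expr <- matrix_as_expr(rbind(g1 = g1, g2 = g2, g3 = g3))
  names(expr)[-1] <- samples
  drugs <- tibble::tibble(sample = samples,
                          dNeg = 0.5 + effect[1] * g1 + rnorm(n, sd = noise),
                          dPos = 0.5 + effect[2] * g2 + rnorm(n, sd = noise),
                          dNull = rnorm(n))
  list(expr = expr, drugs = drugs)
}

test_that("planted effects are retained with the correct label", {
  d <- planted_screen_data(1)
  assoc <- gene_drug_screen(d$expr, d$drugs)
  neg <- assoc[assoc$feature == "g1" & assoc$drug == "dNeg", ]
  pos <- assoc[assoc$feature == "g2" & assoc$drug == "dPos", ]
  expect_equal(neg$label, "sensitive")
  expect_equal(pos$label, "resistant")
  expect_true(all(abs(assoc$rho) > 0.25))
  expect_true(all(assoc$fdr < 0.05))
  # label is sensitive iff rho < 0
  expect_true(all((assoc$rho < 0) == (assoc$label == "sensitive")))
})

test_that("screen matches pairwise spearman_cor results", {
  d <- planted_screen_data(2, n = 40)
  assoc <- gene_drug_screen(d$expr, d$drugs, rs_threshold = 0,
                            fdr_threshold = 1.01)
  tested <- attr(assoc, "tested")
  em <- expr_as_matrix(d$expr)
  for (i in sample(nrow(tested), 5)) {
    ct <- spearman_cor(em[tested$feature[i], ],
                       d$drugs[[tested$drug[i]]])
    expect_equal(tested$rho[i], ct$rho, tolerance = 1e-12)
    expect_equal(tested$p[i], ct$p_value, tolerance = 1e-10)
  }
})

test_that("labeling is anti-symmetric under response negation", {
  d <- planted_screen_data(3)
  flipped <- d$drugs
  flipped[-1] <- -flipped[-1]
  a <- gene_drug_screen(d$expr, d$drugs)
  b <- gene_drug_screen(d$expr, flipped)
  j <- dplyr::inner_join(a, b, by = c("feature", "drug"))
  expect_true(nrow(j) > 0)
  expect_true(all(j$rho.x == -j$rho.y))
  expect_true(all((j$label.x == "sensitive") == (j$label.y == "resistant")))
})

test_that("screens are invariant under monotone response transforms", {
  d <- planted_screen_data(4, n = 60)
  warped <- d$drugs
  warped[-1] <- exp(warped[-1] / 2)
  a <- gene_drug_screen(d$expr, d$drugs, rs_threshold = 0,
                        fdr_threshold = 1.01)
  b <- gene_drug_screen(d$expr, warped, rs_threshold = 0,
                        fdr_threshold = 1.01)
  expect_equal(attr(a, "tested")$rho, attr(b, "tested")$rho,
               tolerance = 1e-12)
})

test_that("boundary |Rs| is excluded by the strict inequality", {
  # build vectors with known rank correlation exactly 0.25 is awkward;
  # instead verify the filter directly around the boundary
  samples <- paste0("s", 1:20)
  set.seed(5)
  x <- rnorm(20)
  expr <- matrix_as_expr(matrix(x, 1, dimnames = list("g", samples)))
  y <- rnorm(20)
  drugs <- tibble::tibble(sample = samples, d = y)
  rho <- spearman_cor(x, y)$rho
  eps <- 1e-12
  at <- gene_drug_screen(expr, drugs, rs_threshold = abs(rho),
                         fdr_threshold = 1.01)
  below <- gene_drug_screen(expr, drugs, rs_threshold = abs(rho) - 1e-6,
                            fdr_threshold = 1.01)
  expect_equal(nrow(at), 0L)       # |Rs| == threshold -> excluded
  expect_equal(nrow(below), 1L)
})

test_that("missing values fall back to pairwise deletion and skipping", {
  d <- planted_screen_data(6, n = 30)
  d$drugs$dNeg[1:28] <- NA        # < 3 shared samples
  assoc <- gene_drug_screen(d$expr, d$drugs)
  sk <- attr(assoc, "skipped")
  expect_true(all(sk$drug == "dNeg"))
  expect_true(all(sk$reason == "too_few_samples"))
  tested <- attr(assoc, "tested")
  expect_false("dNeg" %in% tested$drug)
  expect_true("dPos" %in% tested$drug)
})

test_that("score screen labels planted couplings and skips constants", {
  d <- planted_screen_data(7)
  sc <- setNames(as.numeric(expr_as_matrix(d$expr)["g1", ]),
                 d$drugs$sample)
  assoc <- score_drug_screen(sc, d$drugs)
  neg <- assoc[assoc$drug == "dNeg", ]
  expect_equal(neg$label, "sensitive")
  const <- score_drug_screen(setNames(rep(1, nrow(d$drugs)),
                                      d$drugs$sample), d$drugs)
  expect_equal(nrow(const), 0L)
  expect_true(all(attr(const, "skipped")$reason == "degenerate_feature"))
})

test_that("permuted scores yield no retained associations", {
  d <- planted_screen_data(8, n = 100)
  sc <- as.numeric(expr_as_matrix(d$expr)["g1", ])
  set.seed(88)
  n_hit <- vapply(1:50, function(i) {
    perm <- setNames(sample(sc), d$drugs$sample)
    nrow(score_drug_screen(perm, d$drugs))
  }, numeric(1))
  expect_gte(mean(n_hit == 0), 0.95)
})

test_that("cag_bias detects a planted shift and matches the Fisher oracle", {
  set.seed(9)
  genes <- paste0("g", 1:4)
  hi <- paste0("h", 1:100)
  lo <- paste0("l", 1:100)
  mk_layer <- function(shift_gene = NULL, shift = 0) {
    m <- matrix(rnorm(4 * 200), 4, 200,
                dimnames = list(genes, c(hi, lo)))
    if (!is.null(shift_gene)) m[shift_gene, hi] <- m[shift_gene, hi] + shift
    matrix_as_expr(m)
  }
  mut <- matrix(0, 4, 200, dimnames = list(genes, c(hi, lo)))
  mut["g2", hi[1:20]] <- 1
  mut["g2", lo[1:2]] <- 1
  layers <- list(mrna = mk_layer("g1", 1.5), mutation = matrix_as_expr(mut))
  res <- cag_bias(hi, lo, layers)
  g1 <- res[res$gene == "g1" & res$layer == "mrna", ]
  expect_lt(g1$fdr, 0.05)
  expect_equal(g1$statistic, 1.5, tolerance = 0.15)
  expect_equal(g1$biased_group, "high")
  g2 <- res[res$gene == "g2" & res$layer == "mutation", ]
  # hypergeometric oracle for the 20/100 vs 2/100 table (two-sided Fisher:
  # sum of all tables with probability <= observed)
  probs <- dhyper(0:22, 100, 100, 22)
  p_oracle <- sum(probs[probs <= dhyper(20, 100, 100, 22) + 1e-12])
  expect_equal(g2$p, p_oracle, tolerance = 1e-9)
  expect_equal(g2$biased_group, "high")
  # identical groups: nothing at FDR < 0.05 on a null layer
  null_res <- cag_bias(hi, lo, list(mrna = mk_layer()))
  expect_equal(sum(null_res$fdr < 0.05, na.rm = TRUE), 0L)
  # missing gene recorded as untested
  part <- cag_bias(hi, lo, list(mrna = mk_layer()), genes = c(genes, "gX"))
  expect_false(part$tested[part$gene == "gX"])
})

test_that("the integrated FFL-drug network wires drugs to features", {
  tri <- tibble::tibble(tf = "TF1", mirna = "miR1", target = "G1",
                        ffl_type = "TF-FFL")
  bare <- ffl_drug_network(tri)
  expect_equal(sum(igraph::V(bare)$class == "drug"), 0L)
  assoc <- tibble::tibble(feature = "G1", drug = "DrugX", rho = -0.5,
                          p = 1e-4, fdr = 1e-3, label = "sensitive")
  g <- ffl_drug_network(tri, gene_assocs = assoc)
  expect_equal(sum(igraph::V(g)$class == "drug"), 1L)
  ed <- igraph::E(g)[igraph::E(g)$relation == "association"]
  expect_equal(length(ed), 1L)
  expect_equal(ed$label, "sensitive")
  # coherent pattern: gene and TF sensitive, miRNA resistant, same drug
  multi <- tibble::tibble(
    feature = c("G1", "TF1", "miR1"), drug = "DrugX",
    rho = c(-0.5, -0.4, 0.45), p = 1e-4, fdr = 1e-3,
    label = c("sensitive", "sensitive", "resistant"))
  g2 <- ffl_drug_network(tri, gene_assocs = multi[1, ],
                         tf_assocs = multi[2, ], mirna_assocs = multi[3, ])
  lab <- igraph::E(g2)$label[igraph::E(g2)$relation == "association"]
  expect_setequal(lab, c("sensitive", "sensitive", "resistant"))
})
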