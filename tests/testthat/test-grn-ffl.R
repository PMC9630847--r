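test_that("prior integration keeps >=2-source pairs with their evidence", {
  s1 <- tibble::tibble(mirna = c("m1", "m2"), target = c("gA", "gB"))
  s2 <- tibble::tibble(mirna = c("m1", "m3"), target = c("gA", "gC"))
  kept <- integrate_mirna_priors(list(miRDB = s1, PITA = s2))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$regulator, "m1")
  expect_equal(kept$evidence, "PITA;miRDB")
  expect_equal(kept$n_sources, 2L)
  expect_error(integrate_mirna_priors(list(s1), min_sources = 2), "at least")
})

test_that("prior integration equals brute-force source counting", {
  set.seed(81)
  for (rep in 1:5) {
    srcs <- lapply(1:4, function(i) {
      g <- expand.grid(mirna = paste0("m", 1:6), target = paste0("g", 1:8),
                       stringsAsFactors = FALSE)
      g[runif(nrow(g)) < 0.2, ]
    })
    kept <- integrate_mirna_priors(srcs, min_sources = 2)
    counts <- table(unlist(lapply(srcs, function(s) {
      unique(paste(s$mirna, s$target))
    })))
    want <- sort(names(counts)[counts >= 2])
    expect_equal(paste(kept$regulator, kept$target), want)
  }
})

test_that("FFL enumeration reproduces the canonical type examples", {
  tg <- data.frame(regulator = "TF1", target = "g1")
  mg <- data.frame(regulator = "miR1", target = "g1")
  tm <- data.frame(regulator = "TF1", target = "miR1")
  mt <- data.frame(regulator = "miR1", target = "TF1")
  none <- tm[0, ]
  expect_equal(enumerate_ffls(tg, mg, tm, none)$ffl_type, "TF-FFL")
  expect_equal(enumerate_ffls(tg, mg, none, mt)$ffl_type, "miRNA-FFL")
  expect_equal(enumerate_ffls(tg, mg, tm, mt)$ffl_type, "composite-FFL")
  expect_equal(nrow(enumerate_ffls(tg, mg, none, none)), 0L)
})

test_that("FFL enumeration matches brute force on random instances", {
  for (seed in 1:25) {
    es <- random_edge_sets(seed)
    got <- enumerate_ffls(es$tf_gene, es$mirna_gene, es$tf_mirna,
                          es$mirna_tf)
    want <- brute_ffls(es$tf_gene, es$mirna_gene, es$tf_mirna, es$mirna_tf)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    # the three type counts partition the total
    expect_equal(sum(got$ffl_type == "TF-FFL") +
                   sum(got$ffl_type == "miRNA-FFL") +
                   sum(got$ffl_type == "composite-FFL"), nrow(got))
  }
})

test_that("class-inconsistent or self-referential edges are rejected", {
  bad <- data.frame(regulator = "x", target = "x")
  expect_error(enumerate_ffls(bad, bad, bad[0, ], bad[0, ]), "Self-edges")
  mis <- data.frame(regulator = "TF1", target = "g1",
                    regulator_class = "miRNA", target_class = "gene")
  expect_error(enumerate_ffls(mis, mis[0, ], mis[0, ], mis[0, ]),
               "regulator_class")
})

test_that("refinement keeps planted triads and drops wrong-signed ones", {
  cfg <- sim_config(seed = 91, n_tf = 3, n_mirna = 3, n_target = 5,
                    n_samples = 200, edge_density = 0.5, effect_size = 1,
                    noise_sd = 0.3)
  co <- simulate_cohort(cfg)
  tri <- enumerate_ffls_from_edges(co$truth$edges)
  rn <- refine_ffls(tri, co$expr, co$mirna_expr, group = "sim")
  expect_s3_class(rn, "refined_network")
  planted <- co$truth$planted_triads
  recoverable <- planted[planted$ffl_type != "composite-FFL", ]
  found <- dplyr::semi_join(rn$triads, recoverable,
                            by = c("tf", "mirna", "target"))
  expect_equal(nrow(found), nrow(recoverable))
  # every surviving edge carries the required sign
  expect_true(all(rn$triads$tf_gene_rho > 0))
  expect_true(all(rn$triads$mirna_gene_rho < 0))
  expect_true(all(rn$triads$tf_gene_p < 0.05))
  expect_true(all(rn$triads$mirna_gene_p < 0.05))
  # refinement returns a subset of its input
  expect_true(nrow(rn$triads) <= nrow(tri))
  expect_equal(nrow(dplyr::anti_join(
    rn$triads[, c("tf", "mirna", "target")],
    tri[, c("tf", "mirna", "target")],
    by = c("tf", "mirna", "target"))), 0L)
})

test_that("a positively-correlated miRNA-target pair is filtered out", {
  set.seed(92)
  n <- 100
  t_v <- rnorm(n)
  m_v <- t_v + rnorm(n, sd = 0.2)        # miRNA tracks the TF: positive rho
  g_v <- t_v + rnorm(n, sd = 0.2)
  samples <- paste0("s", 1:n)
  em <- rbind(TF1 = t_v, G1 = g_v) + 8
  colnames(em) <- samples
  expr <- matrix_as_expr(em)
  mirna <- matrix_as_expr(matrix(m_v, 1, dimnames = list("miR1", samples)),
                          id_col = "mirna")
  tri <- tibble::tibble(tf = "TF1", mirna = "miR1", target = "G1",
                        ffl_type = "TF-FFL")
  rn <- refine_ffls(tri, expr, mirna)
  expect_equal(nrow(rn$triads), 0L)
})

test_that("tightening the p threshold never adds triads", {
  cfg <- sim_config(seed = 93, n_samples = 60, edge_density = 0.4)
  co <- simulate_cohort(cfg)
  tri <- enumerate_ffls_from_edges(co$truth$edges)
  loose <- refine_ffls(tri, co$expr, co$mirna_expr, p_threshold = 0.2)
  tight <- refine_ffls(tri, co$expr, co$mirna_expr, p_threshold = 0.01)
  key <- function(x) paste(x$tf, x$mirna, x$target)
  expect_true(all(key(tight$triads) %in% key(loose$triads)))
})

test_that("degenerate and missing features are skipped with reasons", {
  samples <- paste0("s", 1:10)
  expr <- matrix_as_expr(matrix(c(rnorm(10), rnorm(10)), 2, byrow = TRUE,
                                dimnames = list(c("TF1", "G1"), samples)))
  mirna <- matrix_as_expr(matrix(rep(5, 10), 1,
                                 dimnames = list("miR1", samples)),
                          id_col = "mirna")
  tri <- tibble::tibble(tf = c("TF1", "TF1"), mirna = c("miR1", "miR9"),
                        target = c("G1", "G1"),
                        ffl_type = c("TF-FFL", "TF-FFL"))
  rn <- refine_ffls(tri, expr, mirna)
  expect_equal(nrow(rn$triads), 0L)
  expect_setequal(rn$skipped$reason,
                  c("degenerate_expression", "missing_feature"))
})

test_that("pan-cancer merge annotates triads with their groups", {
  cfg <- sim_config(seed = 94, n_tf = 3, n_mirna = 3, n_target = 5,
                    n_samples = 120, edge_density = 0.5)
  co <- simulate_cohort(cfg)
  tri <- enumerate_ffls_from_edges(co$truth$edges)
  samples <- setdiff(names(co$expr), "gene")
  g1 <- samples[1:60]
  g2 <- samples[61:120]
  rnA <- refine_ffls(tri, co$expr, co$mirna_expr, samples = g1, group = "A")
  rnB <- refine_ffls(tri, co$expr, co$mirna_expr, samples = g2, group = "B")
  single <- pan_cancer_merge(list(rnA))
  expect_equal(nrow(single), nrow(rnA$triads))
  merged <- pan_cancer_merge(list(rnA, rnB))
  both <- dplyr::semi_join(
    rnA$triads, rnB$triads, by = c("tf", "mirna", "target"))
  expect_equal(sum(merged$n_groups == 2), nrow(both))
  expect_true(all(merged$groups[merged$n_groups == 2] == "A;B"))
  expect_equal(nrow(merged),
               nrow(dplyr::distinct(dplyr::bind_rows(
                 rnA$triads[, 1:3], rnB$triads[, 1:3]))))
})

test_that("tidy and glance summarise a refined network", {
  cfg <- sim_config(seed = 95, n_samples = 80, edge_density = 0.5)
  co <- simulate_cohort(cfg)
  tri <- enumerate_ffls_from_edges(co$truth$edges)
  rn <- refine_ffls(tri, co$expr, co$mirna_expr, group = "glioma")
  expect_identical(generics::tidy(rn), rn$triads)
  gl <- generics::glance(rn)
  expect_equal(gl$n_triads, nrow(rn$triads))
  expect_equal(gl$n_tf_ffl + gl$n_mirna_ffl + gl$n_composite_ffl,
               gl$n_triads)
})
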