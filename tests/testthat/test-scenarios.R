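# scenario-level checks: each block exercises one in-silico experiment on
# the curated subtype exemplars (grids kept coarse to bound runtime)

test_that("subtype exemplars reach their advertised compositions", {
  net <- build_hnscc_network()
  ex <- subtype_exemplars()
  for (lab in names(ex)) {
    rec <- steady_state(net, ex[[lab]], default_initial_state(ex[[lab]]),
                        t_max = 4000, tol = 1e-5)
    expect_true(rec$converged, label = lab)
    expect_equal(classify_steady_state(rec, ex[[lab]]), lab)
  }
})

test_that("immune-desert variants separate the three desert mechanisms", {
  dv <- scenario_immune_desert_variants(
    prolif_factors = c(0.3, 1), exhaustion_factors = c(1, 10),
    treg_factors = c(1, 10))
  expect_error(scenario_immune_desert_variants(prolif_factors = numeric(0)),
               "non-empty")

  lowp <- dv[dv$prolif == 0.3 & dv$exhaustion == 1 & dv$treg == 1, ]
  exh <- dv[dv$prolif == 1 & dv$exhaustion == 10 & dv$treg == 1, ]
  trg <- dv[dv$prolif == 0.3 & dv$exhaustion == 1 & dv$treg == 10, ]
  expect_equal(lowp$mechanism, "low_proliferation")
  expect_equal(exh$mechanism, "exhaustion_driven")
  expect_equal(trg$mechanism, "treg_driven")
  expect_true(all(c(lowp$label, exh$label, trg$label) == "immune_desert"))

  # only the exhaustion-driven desert recovers killer T cells under ICI
  expect_false(lowp$responds)
  expect_true(exh$responds)
  expect_false(trg$responds)
  # the Treg-driven desert is regulatory-T rich (TReg near capacity)
  expect_gt(trg$pre_TReg, 3 * lowp$pre_TReg)
})

test_that("ICI response is subtype specific", {
  ex <- subtype_exemplars()
  r <- scenario_ici_by_subtype(
    ex[c("immune_dominated", "fibro_dominated")],
    Ia_grid = c(0.05, 0.9), resource_factors = 1)
  s <- r$summary

  imm <- s[s$subtype == "immune_dominated", ]
  fib <- s[s$subtype == "fibro_dominated", ]
  # immune-dominated: drastic tumor shrinkage and a reduced CAF pool
  expect_lt(imm$post_tumor, 0.05 * imm$pre_tumor)
  expect_lt(imm$post_CAF, imm$pre_CAF)
  # fibro-dominated: tumor and CAF essentially unchanged
  expect_gt(fib$post_tumor, 0.9 * fib$pre_tumor)
  expect_lt(abs(fib$post_CAF - fib$pre_CAF), 0.05 * fib$pre_CAF)

  # at frozen low accessibility the CAF pool barely moves; response
  # deteriorates as accessibility is lost
  ia <- r$ia_scan[order(r$ia_scan$Ia), ]
  expect_lt(abs(ia$post_CAF[1] - ia$pre_CAF[1]), 0.05 * ia$pre_CAF[1])
  expect_true(all(diff(ia$post_tumor) <= 1e-6))
})

test_that("zero dose is the identity for every subtype", {
  ex <- subtype_exemplars()
  net <- build_hnscc_network()
  for (lab in c("immune_desert", "fibro_dominated")) {
    p <- ex[[lab]]
    # the zero-dose model is bitwise identical; the post phase continues
    # the integration from the converged state, so any difference is
    # residual drift on the slow manifold
    mod <- apply_anti_pd1(net, p, dose = 0)
    expect_identical(mod$params, p)
    expect_identical(length(mod$network$edges), length(net$edges))
    res <- ici_response(net, p, dose = 0)
    expect_equal(res$post$state, res$pre$state, tolerance = 2e-3)
  }
})

test_that("the IL-2 spike threshold is finite above the rescue floor and infinite below", {
  ex <- subtype_exemplars()
  # boosted IL-2 autocrine gain: a finite spike threshold exists
  p <- ex$immune_desert
  p[["Kpara_IL2_TK"]] <- p[["Kpara_IL2_TK"]] * 10
  th <- scenario_il2_threshold(p, amplitudes = 10^seq(0, 4, length.out = 5))
  expect_true(is.finite(th$threshold) && th$threshold > 0)
  expect_equal(th$scan$label[1], "immune_desert") # amplitude 0 unchanged
  expect_false(th$scan$label[nrow(th$scan)] %in%
                 c("desert", "immune_desert"))

  # severed IL-2 coupling: no amplitude can escape the desert
  p0 <- ex$immune_desert
  p0[["Kpara_IL2_TK"]] <- 0
  th0 <- scenario_il2_threshold(p0, amplitudes = c(10, 1e4))
  expect_identical(th0$threshold, Inf)
})

test_that("OPN and LIF knockouts reshape the fibro-dominated TME", {
  ex <- subtype_exemplars()
  ok <- scenario_opn_lif_knockout(ex$fibro_dominated,
                                  opn_fractions = c(0, 0.5, 1))
  sc <- ok$scan
  base <- sc[sc$arm == "lif_present" & sc$opn_fraction == 0, ]
  both <- sc[sc$arm == "lif_knockout" & sc$opn_fraction == 1, ]
  lif_only <- sc[sc$arm == "lif_knockout" & sc$opn_fraction == 0, ]

  # full OPN + LIF knockout: CAF collapses, accessibility is restored
  expect_lt(both$CAF, base$CAF)
  expect_gt(both$Ia, base$Ia)
  expect_equal(both$label, "fibro_desert")

  # the LIF arm improves accessibility at every OPN fraction
  for (f in unique(sc$opn_fraction)) {
    expect_gt(sc$Ia[sc$arm == "lif_knockout" & sc$opn_fraction == f],
              sc$Ia[sc$arm == "lif_present" & sc$opn_fraction == f])
  }
  # a LIF-only knockout helps but does not leave the fibro-dominated state
  expect_gt(lif_only$Ia, base$Ia)
  expect_equal(lif_only$label, "fibro_dominated")
  expect_true(all(is.finite(ok$thresholds)))
})

test_that("random fixture draws integrate without solver failures", {
  net <- build_hnscc_network()
  ok <- 0L
  n <- 60L
  for (seed in seq_len(n)) {
    p <- random_parameter_set(seed, spread = 3)
    x0 <- random_initial_state(seed + 4000, p)
    res <- try(integrate_tme(net, p, x0, t_end = 100,
                             times = c(0, 50, 100)), silent = TRUE)
    if (!inherits(res, "try-error")) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.95 * n))
})

test_that("group medoids are drawn from their own groups", {
  d <- sweep_design(n_samples = 40, seed = 5)
  sw <- run_sweep(d, t_max = 800, tol = 1e-4)
  reps <- representative_parameters(sw)
  expect_true(length(reps) >= 1)
  net <- build_hnscc_network()
  for (lab in names(reps)) {
    rec <- steady_state(net, reps[[lab]],
                        default_initial_state(reps[[lab]]),
                        t_max = 800, tol = 1e-4)
    expect_equal(classify_steady_state(rec, reps[[lab]]), lab)
  }
})
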