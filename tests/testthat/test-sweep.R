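test_that("sweep designs validate their inputs", {
  expect_error(sweep_design(varied = list()), "empty")
  expect_error(sweep_design(varied = list(not_a_param = c(0.1, 10))),
               "registry")
  expect_error(sweep_design(varied = list(Kprol_CAF = c(-1, 1))), "positive")
})

test_that("latin-hypercube sampling is seeded and respects its bounds", {
  d <- sweep_design(n_samples = 5, seed = 7)
  expect_identical(sample_parameters(d), sample_parameters(d))

  # degenerate [1, 1] ranges reproduce the nominal registry
  dd <- sweep_design(varied = list(Kprol_CAF = c(1, 1), KD_TKp = c(1, 1)),
                     n_samples = 3, seed = 1)
  for (p in sample_parameters(dd)) expect_equal(p, nominal_parameters())

  # marginals stay inside the declared multiplicative range
  d2 <- sweep_design(varied = list(Kprol_CAF = c(0.1, 10)),
                     n_samples = 200, seed = 3)
  vals <- vapply(sample_parameters(d2), `[[`, numeric(1), "Kprol_CAF")
  nom <- nominal_parameters()[["Kprol_CAF"]]
  expect_true(all(vals >= 0.1 * nom & vals <= 10 * nom))
  # and roughly cover it (log-range at least half used)
  expect_gt(log10(max(vals) / min(vals)), 1)
})

test_that("zeta reproduces hand computations and log additivity", {
  nodes <- rbind(node_spec("A", "cell_state"), node_spec("B", "cell_state"),
                 node_spec("K", "cell_state"))
  edges <- list(
    edge_spec("proliferation", "A", params = c(Kprol = "KpA")),
    edge_spec("death", "A", params = c(KD = "KdA")),
    edge_spec("proliferation", "B", params = c(Kprol = "KpB")),
    edge_spec("death", "B", params = c(KD = "KdB")),
    edge_spec("paracrine", "B", "A",
              params = c(Kpara = "KparaAB", V = "VAB")),
    edge_spec("conversion", "A", "B", params = c(Kconv = "KcBA")),
    edge_spec("proliferation", "K", params = c(Kprol = "KpK")),
    edge_spec("death", "K", params = c(KD = "KdK")),
    edge_spec("elimination", "B", "K", params = c(Kkill = "KkB"))
  )
  pools <- list(list(members = "A", cap_key = "xA"),
                list(members = "B", cap_key = "xB"),
                list(members = "K", cap_key = "xK"))
  net <- network_spec(nodes, edges, pools = pools)
  p <- c(KpA = 1, KdA = 1, KpB = 2, KdB = 0.25, KparaAB = 1, VAB = 10,
         KcBA = 0.5, KpK = 1, KdK = 1, KkB = 0.25, xA = 1, xB = 1, xK = 1)

  # A: Kprol 1, no paracrine in-edges, sinks KD = 1 -> zeta 0
  expect_equal(zeta("A", net, p), 0)
  # B: Fmax = 2 * (1 + 1) = 4; sinks = kill + conversion + death = 1
  expect_equal(zeta("B", net, p), log(4))
  # scaling the proliferation rate by c shifts zeta by exactly log(c)
  for (cc in c(0.1, 3, 42)) {
    p2 <- p; p2[["KpB"]] <- p[["KpB"]] * cc
    expect_equal(zeta("B", net, p2) - zeta("B", net, p), log(cc))
  }
  # zero-sink cell yields the +Inf sentinel with a warning
  p3 <- p; p3[c("KdK")] <- 0
  expect_warning(zk <- zeta("K", net, p3), "zero")
  expect_identical(zk, Inf)
  expect_error(zeta("nope", net, p), "not a cell-state")
})

test_that("zeta on the atlas responds to tumor proliferation scaling", {
  net <- build_hnscc_network()
  p <- nominal_parameters()
  z0 <- zeta_total_tumor(net, p)
  p2 <- p
  p2[c("Kprol_C0", "Kprol_Cneg", "Kprol_Cpos")] <-
    p[c("Kprol_C0", "Kprol_Cneg", "Kprol_Cpos")] * 2
  expect_equal(zeta_total_tumor(net, p2) - z0, log(2))
})

test_that("classification assigns exactly one of the five labels", {
  p <- nominal_parameters()
  mk <- function(tk, caf, tumor, conv = TRUE) {
    list(converged = conv,
         derived = list(killer_T_total = tk, CAF = caf, total_tumor = tumor,
                        pdl1_ratio = 1, pdl1_defined = TRUE, Ia = 0.5))
  }
  expect_equal(classify_steady_state(mk(0, 0, 5000), p), "desert")
  expect_equal(classify_steady_state(mk(0, 1500, 9000), p), "immune_desert")
  expect_equal(classify_steady_state(mk(1500, 0, 9000), p), "fibro_desert")
  expect_equal(classify_steady_state(mk(1500, 1600, 9000), p),
               "fibro_dominated")
  expect_equal(classify_steady_state(mk(1700, 900, 9000), p),
               "immune_dominated")
  expect_equal(classify_steady_state(mk(1, 1, 1, conv = FALSE), p),
               "unlabeled")
})

test_that("a seeded sweep is reproducible and partitions its samples", {
  d <- sweep_design(n_samples = 24, seed = 11)
  s1 <- run_sweep(d, t_max = 800, tol = 1e-4)
  s2 <- run_sweep(d, t_max = 800, tol = 1e-4)
  expect_identical(s1$samples, s2$samples)
  labs <- s1$samples$label
  expect_true(all(labs %in% c("desert", "immune_desert", "fibro_desert",
                              "immune_dominated", "fibro_dominated",
                              "unlabeled")))
  conv <- sum(s1$samples$converged & labs != "unlabeled")
  expect_equal(sum(s1$groups$n), conv)
})

test_that("local sensitivities recover logistic elasticities", {
  net <- toy_logistic()
  p <- toy_logistic_params(Kprol = 1, xmax = 10, KD = 0)
  out <- local_sensitivity(net, p, parameters = c("Kprol_A", "xmax_A"),
                           targets = "A", x0 = c(A = 0.5), t_max = 400)
  # the logistic fixed point is xmax: elasticity 0 in Kprol, 1 in xmax
  expect_equal(out$value[out$parameter == "Kprol_A"], 0, tolerance = 1e-3)
  expect_equal(out$value[out$parameter == "xmax_A"], 1, tolerance = 1e-3)
  expect_false(any(out$flagged))
})

test_that("structurally disconnected parameters have zero sensitivity", {
  net <- build_hnscc_network()
  p <- nominal_parameters()
  # ICAM1 is a read-out species: its degradation rate cannot reach the
  # tumor, killer-T or CAF populations
  out <- local_sensitivity(net, p, parameters = "KD_ICAM1",
                           t_max = 1000, tol = 1e-5)
  expect_true(all(abs(out$value) < 1e-6))
})
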