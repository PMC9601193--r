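test_that("scenario invariants are enforced", {
  expect_error(scenario("bad", effects = c(glutamine = -1)), "fold-changes")
  expect_error(scenario("bad", n_treated = 1), "replicates")
  expect_error(scenario("bad", outlier_rate = 0.5), "outlier_rate")
  expect_error(scenario("bad", effects = c(2)), "named")
})

test_that("built-in scenarios carry the published signature structure", {
  scns <- builtin_scenarios()
  expect_length(scns$pgp_inhibitor$effects, 11)
  expect_true(all(scns$pgp_inhibitor$effects > 1))
  bcrp <- scns$bcrp_inhibitor$effects
  expect_length(bcrp, 4)
  expect_equal(sum(bcrp < 1), 3)
  expect_equal(sum(bcrp > 1), 1)
  expect_gt(bcrp["pantothenate"], 1)
  mrp2 <- scns$mrp2_inhibitor$effects
  expect_length(mrp2, 9)
  expect_lt(mrp2["acetylcarnitine"], 1)
  expect_equal(sum(mrp2 > 1), 8)
  expect_length(scns$vehicle$effects, 0)
  expect_length(scns$substrate_nonInhibitor$effects, 0)
  for (s in scns) expect_equal(c(s$n_treated, s$n_control), c(6, 6))
})

test_that("generated tables are deterministic in the seed and honest about ground truth", {
  scns <- builtin_scenarios()
  a <- generate_peak_table(scns$pgp_inhibitor, seed = 42)
  b <- generate_peak_table(scns$pgp_inhibitor, seed = 42)
  expect_identical(a$table$areas, b$table$areas)
  d <- generate_peak_table(scns$pgp_inhibitor, seed = 43)
  expect_false(identical(a$table$areas, d$table$areas))

  expect_setequal(a$truth$altered_metabolites$metabolite,
                  names(scns$pgp_inhibitor$effects))
  expect_true(all(a$truth$altered_metabolites$direction == "up"))
  expect_equal(nrow(a$truth$altered_metabolites), 11)

  veh <- generate_peak_table(scns$vehicle, seed = 1)
  expect_equal(nrow(veh$truth$altered_metabolites), 0)
  expect_length(veh$truth$outlier_samples, 0)
})

test_that("generator enforces panel preconditions and spans 3 decades", {
  scns <- builtin_scenarios()
  expect_error(generate_peak_table(scns$pgp_inhibitor, n_metabolites = 10),
               "n_metabolites")
  bad <- scenario("bad", transporter = "pgp", role = "inhibitor",
                  effects = c(unobtainium = 2))
  expect_error(generate_peak_table(bad, seed = 1), "unobtainium")

  g <- generate_peak_table(scns$vehicle, seed = 5)
  med <- apply(g$table$areas[, analysis_cols <- setdiff(colnames(g$table$areas),
                                                        "olomoucine")], 2, median)
  expect_gte(log10(max(med) / min(med)), 3)
})

test_that("the spiked control is near-constant and planted effects survive normalization", {
  scns <- builtin_scenarios()
  g <- generate_peak_table(scns$pgp_inhibitor, seed = 7)
  olo <- g$table$areas[, "olomoucine"]
  expect_lte(stats::sd(olo) / mean(olo), 0.02)

  # planted-effect fidelity: treated/control mean ratio approaches the
  # fold-change as noise vanishes
  quiet <- scns$pgp_inhibitor
  quiet$noise_cv <- 1e-4
  gq <- generate_peak_table(quiet, seed = 11)
  norm <- total_sum_normalize(gq$table)
  tr <- norm$groups == "treated"
  ratio <- mean(norm$areas[tr, "glutamine"]) / mean(norm$areas[!tr, "glutamine"])
  expect_equal(ratio, 1.6, tolerance = 0.02)
})

test_that("experiment sets share ground truth across distinct sub-seeds", {
  es <- generate_experiment_set("pgp", seed = 1)
  expect_length(es, 4)
  kinds <- vapply(es, function(e) e$meta$kind, character(1))
  expect_equal(sum(kinds == "inhibitor"), 3)
  expect_equal(sum(kinds == "knockout"), 1)
  truths <- lapply(es, function(e) sort(e$truth$altered_metabolites$metabolite))
  for (t2 in truths[-1]) expect_equal(t2, truths[[1]])
  expect_false(identical(es[[1]]$table$areas, es[[2]]$table$areas))

  es_m <- generate_experiment_set("mrp2", seed = 7)
  for (e in es_m) expect_equal(nrow(e$truth$altered_metabolites), 9)
  expect_error(generate_experiment_set("oatp", seed = 1), "unknown transporter")
})

test_that("transport series round-trips papp and respects noise", {
  s <- generate_transport_series(1e-6, noise_cv = 0, seed = 1)
  expect_equal(papp(s), 1e-6, tolerance = 1e-12)

  flat <- generate_transport_series(0, noise_cv = 0, seed = 1)
  expect_true(all(flat$receiver_concentration == 0))
  expect_equal(papp(flat), 0)

  expect_error(generate_transport_series(1e-6, vr = -1), "positive")
  expect_error(generate_transport_series(1e-6, n_timepoints = 2), "3 time points")

  # Monte-Carlo recovery with 5% noise across 100 seeds
  rel_err <- vapply(1:100, function(seed) {
    s <- generate_transport_series(1e-6, n_timepoints = 5, noise_cv = 0.05,
                                   seed = seed)
    abs(papp(s) - 1e-6) / 1e-6
  }, numeric(1))
  expect_true(all(rel_err < 0.15))
})
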