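test_that("percent change follows 100 x (treated - control)/control", {
  mk <- function(treated, control) {
    X <- rbind(matrix(rep(treated, each = 2), 2),
               matrix(rep(control, each = 2), 2))
    dimnames(X) <- list(paste0("s", 1:4), paste0("m", seq_along(treated)))
    tb <- peak_table(X, c("treated", "treated", "control", "control"),
                     normalized = TRUE)
    percent_change_table(tb)
  }
  pc <- mk(c(2, 1, 0.5), c(1, 1, 1))
  expect_equal(pc$percent_change, c(100, 0, -50))

  # invariance to common rescaling of both groups
  pc10 <- mk(10 * c(2, 1, 0.5), 10 * c(1, 1, 1))
  expect_equal(pc10$percent_change, pc$percent_change)

  # zero control mean -> undefined, not dropped
  pc0 <- mk(c(1), c(0))
  expect_equal(nrow(pc0), 1)
  expect_true(is.na(pc0$percent_change))
})

test_that("significance tiers map exactly to the star conventions", {
  X <- matrix(1, 4, 1, dimnames = list(paste0("s", 1:4), "m"))
  tb <- peak_table(X, c("treated", "treated", "control", "control"),
                   normalized = TRUE)
  pc <- percent_change_table(tb)
  expect_equal(pc$tier, "ns")
  expect_identical(effluxsig:::significance_tier(c(0.049, 0.05, 0.009, 9e-4, 9e-5, 0.6)),
                   c("*", "ns", "**", "***", "****", "ns"))
})

test_that("Mann-Whitney exact p matches the enumeration oracle on tie-free samples", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)

  set.seed(6)
  for (rep in 1:30) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    vals <- sample(1000, n1 + n2)  # tie-free
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    got <- mann_whitney_u(a, b)
    want <- mw_enum_oracle(a, b)
    expect_equal(got$u, want$u)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney is symmetric and handles ties and degeneracy", {
  a <- c(1.2, 3.4, 2.2, 8)
  b <- c(0.5, 3.4, 9.9)
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("packaged reference signatures match the published membership", {
  sigs <- reference_signatures()
  expect_equal(nrow(sigs$pgp$members), 11)
  expect_true(all(sigs$pgp$members$direction == "up"))
  expect_true(all(c("pyridoxine", "glutamine", "arginine", "creatinine",
                    "leucine", "methylcysteine", "phenylalanine", "methionine",
                    "threonine", "nicotinamide", "pantothenate") %in%
                    sigs$pgp$members$metabolite))

  expect_equal(nrow(sigs$bcrp$members), 4)
  down <- sigs$bcrp$members$metabolite[sigs$bcrp$members$direction == "down"]
  expect_setequal(down, c("glutamate", "hypoxanthine", "xanthine"))
  expect_equal(sigs$bcrp$members$metabolite[sigs$bcrp$members$direction == "up"],
               "pantothenate")

  expect_equal(nrow(sigs$mrp2$members), 9)
  expect_equal(sigs$mrp2$members$metabolite[sigs$mrp2$members$direction == "down"],
               "acetylcarnitine")
  expect_equal(sum(sigs$mrp2$members$direction == "up"), 8)
})

test_that("signature derivation recovers the planted panel on a generated set", {
  es <- generate_experiment_set("pgp", seed = 1)
  sig <- derive_from_set(es)
  expect_setequal(sig$members$metabolite,
                  es[[1]]$truth$altered_metabolites$metabolite)
  expect_true(all(sig$members$direction == "up"))
})

test_that("derivation rules: threshold, direction conflicts, order invariance", {
  mk_exp <- function(vips, pcs, kind, compound) {
    list(vip = structure(list(vip = vips, threshold = 0.75), class = "vip_result"),
         changes = structure(data.frame(metabolite = names(pcs),
                                        percent_change = unname(pcs),
                                        stringsAsFactors = FALSE),
                             class = c("percent_change_table", "data.frame")),
         kind = kind, compound = compound)
  }
  vips <- c(a = 2, b = 1.5, c = 0.1)
  e1 <- mk_exp(vips, c(a = 30, b = 20, c = 1), "inhibitor", "inh1")
  e2 <- mk_exp(vips, c(a = 25, b = -15, c = 2), "knockout", "ko")

  sig <- derive_signature(list(e1, e2))
  expect_equal(sig$members$metabolite, "a")   # b conflicts, c fails VIP
  expect_equal(sig$members$direction, "up")
  expect_true("b" %in% names(sig$excluded))

  # order invariance
  sig_rev <- derive_signature(list(e2, e1))
  expect_equal(sig_rev$members, sig$members)

  # infinite threshold empties the signature
  expect_equal(nrow(derive_signature(list(e1, e2), vip_threshold = Inf)$members), 0)

  # validation experiments direction-gate but never VIP-gate
  e3 <- mk_exp(c(a = 0.1, b = 0.1, c = 0.1), c(a = 40, b = 10, c = 1),
               "inhibitor", "extra")
  e3$validation <- TRUE
  sig_v <- derive_signature(list(e1, e2, e3))
  expect_equal(sig_v$members$metabolite, "a")
  e3_conflict <- mk_exp(c(a = 0.1), c(a = -40), "inhibitor", "extra")
  e3_conflict$validation <- TRUE
  sig_c <- derive_signature(list(e1, e2, e3_conflict))
  expect_false("a" %in% sig_c$members$metabolite)
  expect_true("a" %in% names(sig_c$excluded))

  expect_error(derive_signature(list(e1)), "knockout")
})

test_that("concentration trend detects monotone dose response", {
  mk_pc <- function(pcs) {
    structure(data.frame(metabolite = names(pcs), percent_change = unname(pcs),
                         stringsAsFactors = FALSE),
              class = c("percent_change_table", "data.frame"))
  }
  rising <- lapply(c(10, 20, 35, 60), function(v) mk_pc(c(glutamine = v)))
  tr <- concentration_trend(rising, "glutamine", doses = c(0.625, 1.25, 2.5, 5))
  expect_equal(tr$rho, 1)
  expect_lt(tr$p, 0.1)

  flat <- lapply(rep(5, 4), function(v) mk_pc(c(glutamine = v)))
  expect_equal(concentration_trend(flat, "glutamine"), list(rho = 0, p = 1))
  expect_error(concentration_trend(rising[1:2], "glutamine"), "3 dose")
  expect_error(concentration_trend(rising, "absent"), "absent")
})

test_that("dose-attenuated generator series produce a perfect rank trend", {
  scn <- builtin_scenarios()$pgp_inhibitor
  scn$noise_cv <- 0.05
  tabs <- lapply(scn$dose_series$attenuation, function(a) {
    g <- generate_peak_table(attenuate_scenario(scn, a), seed = 5)
    percent_change_table(total_sum_normalize(g$table))
  })
  for (m in c("glutamine", "pyridoxine")) {
    expect_equal(concentration_trend(tabs, m, doses = scn$dose_series$doses)$rho, 1)
  }
})
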