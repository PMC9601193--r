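#' Define a simulation scenario
#'
#' A scenario describes one treated-vs-control peak-area experiment: which
#' transporter is perturbed, in what role (chemical inhibitor, knockout
#' line, non-inhibitor substrate or vehicle), which metabolites respond and
#' by what fold-change, the replicate design and the noise model.
#'
#' @param name scenario name.
#' @param transporter one of `"pgp"`, `"bcrp"`, `"mrp2"`, `"none"`.
#' @param role one of `"inhibitor"`, `"knockout"`, `"substrate"`, `"vehicle"`.
#' @param effects named numeric vector of fold-changes (> 0) applied to
#'   treated samples; a fold-change of 1 means no effect.
#' @param n_treated,n_control replicate wells per group (each >= 2).
#' @param noise_cv multiplicative replicate noise, as a CV fraction.
#' @param outlier_rate per-sample probability of a gross composition
#'   distortion (in `[0, 0.5)`).
#' @param dose_series optional list with elements `doses` (increasing dose
#'   levels) and `attenuation` (per-dose effect attenuation factors in
#'   `(0, 1]`, same length).
#' @param compound compound label used in reports.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, transporter = c("none", "pgp", "bcrp", "mrp2"),
                     role = c("vehicle", "inhibitor", "knockout", "substrate"),
                     effects = numeric(0), n_treated = 6, n_control = 6,
                     noise_cv = 0.08, outlier_rate = 0, dose_series = NULL,
                     compound = name) {
  transporter <- match.arg(transporter)
  role <- match.arg(role)
  effects <- unlist(effects)
  if (length(effects) && (is.null(names(effects)) || any(!nzchar(names(effects))))) {
    stop("'effects' must be a named vector of fold-changes")
  }
  if (any(effects <= 0)) stop("all fold-changes must be > 0")
  if (n_treated < 2 || n_control < 2) stop("need >= 2 replicates per group")
  if (outlier_rate < 0 || outlier_rate >= 0.5) stop("outlier_rate must be in [0, 0.5)")
  if (!is.null(dose_series)) {
    stopifnot(length(dose_series$doses) == length(dose_series$attenuation),
              all(dose_series$attenuation > 0 & dose_series$attenuation <= 1))
  }
  structure(list(name = name, transporter = transporter, role = role,
                 effects = effects, n_treated = n_treated, n_control = n_control,
                 noise_cv = noise_cv, outlier_rate = outlier_rate,
                 dose_series = dose_series, compound = compound),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %s %s, %d+%d replicates, noise CV %.0f%%, %d effect(s)\n",
              x$name, x$transporter, x$role, x$n_treated, x$n_control,
              100 * x$noise_cv, length(x$effects)))
  invisible(x)
}

# Published consensus signature metabolites (direction of change under
# transporter inhibition / knockout).
signature_members <- list(
  pgp = c(pyridoxine = "up", glutamine = "up", arginine = "up",
          creatinine = "up", leucine = "up", methylcysteine = "up",
          phenylalanine = "up", methionine = "up", threonine = "up",
          nicotinamide = "up", pantothenate = "up"),
  bcrp = c(glutamate = "down", hypoxanthine = "down", xanthine = "down",
           pantothenate = "up"),
  mrp2 = c(arginine = "up", `S-adenosyl-L-homocysteine` = "up",
           threonine = "up", serine = "up", `S-adenosyl-L-methionine` = "up",
           pantothenate = "up", alanine = "up", carnitine = "up",
           `acetylcarnitine` = "down")
)

# default planted fold-changes; calibration choices, not measured values
.fc_up <- 1.6
.fc_down <- 0.6

direction_effects <- function(dirs) {
  stats::setNames(ifelse(dirs == "up", .fc_up, .fc_down), names(dirs))
}

#' Built-in simulation scenarios
#'
#' Returns the packaged scenario set: for each transporter an inhibitor and
#' a knockout scenario planting that transporter's signature directions
#' (fold-change 1.6 for increases, 0.6 for decreases — calibration defaults,
#' not measured effect sizes), plus an effect-free non-inhibitor substrate
#' and a vehicle scenario. All use 6 treated + 6 control replicates.
#'
#' @return Named list of [scenario()] objects: `pgp_inhibitor`, `pgp_ko`,
#'   `bcrp_inhibitor`, `bcrp_ko`, `mrp2_inhibitor`, `mrp2_ko`,
#'   `substrate_nonInhibitor`, `vehicle`.
#' @export
builtin_scenarios <- function() {
  main <- c(pgp = "zosuquidar", bcrp = "Ko143", mrp2 = "MK571")
  out <- list()
  for (tr in c("pgp", "bcrp", "mrp2")) {
    eff <- direction_effects(signature_members[[tr]])
    out[[paste0(tr, "_inhibitor")]] <- scenario(
      paste0(tr, "_inhibitor"), transporter = tr, role = "inhibitor",
      effects = eff, compound = main[[tr]],
      dose_series = list(doses = c(0.625, 1.25, 2.5, 5),
                         attenuation = c(0.25, 0.5, 0.75, 1)))
    out[[paste0(tr, "_ko")]] <- scenario(
      paste0(tr, "_ko"), transporter = tr, role = "knockout",
      effects = eff, compound = paste0(toupper(tr), " KO"))
  }
  out$substrate_nonInhibitor <- scenario("substrate_nonInhibitor",
                                         transporter = "none", role = "substrate",
                                         compound = "substrate")
  out$vehicle <- scenario("vehicle", transporter = "none", role = "vehicle",
                          compound = "DMSO")
  out
}

#' Attenuate a scenario's effects for a dose level
#'
#' Shrinks every planted fold-change toward 1 by the attenuation factor
#' `a`: `fc' = 1 + a * (fc - 1)`, emulating sub-maximal inhibitor doses.
#'
#' @param scn a [scenario()].
#' @param a attenuation factor in `(0, 1]`.
#' @return The attenuated [scenario()].
#' @export
attenuate_scenario <- function(scn, a) {
  stopifnot(inherits(scn, "scenario"), a > 0, a <= 1)
  scn$effects <- 1 + a * (scn$effects - 1)
  scn
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic peak-area experiment
#'
#' Emulates one treated-vs-control targeted LC-MS run. Baseline median
#' areas span more than three orders of magnitude across metabolites;
#' treated samples carry the scenario's multiplicative fold-changes; every
#' sample gets a log-normal size factor (CV 10%, removed by total-sum
#' normalization) and multiplicative replicate noise at the scenario's
#' `noise_cv`; outlier samples (probability `outlier_rate`) have a random
#' half of their metabolites distorted five-fold; a spiked olomoucine
#' instrument-control analyte is held at CV 1%. Identical
#' `(scenario, n_metabolites, seed)` reproduce the table bit-for-bit.
#'
#' @param scn a [scenario()].
#' @param n_metabolites size of the quantified panel (excluding the spiked
#'   control); must cover all named effect metabolites.
#' @param seed integer seed.
#' @return A list with elements `table` (a raw [peak_table()]) and `truth`
#'   (ground truth: `altered_metabolites` data frame with columns
#'   `metabolite`, `direction`, `fold_change`; and `outlier_samples`).
#' @export
generate_peak_table <- function(scn, n_metabolites = 60, seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  named <- unique(unlist(lapply(signature_members, names)))
  if (n_metabolites < length(named)) {
    stop(sprintf("n_metabolites must be >= %d to hold all named metabolites",
                 length(named)))
  }
  n_fill <- n_metabolites - length(named)
  mets <- c(named, if (n_fill) sprintf("met_%03d", seq_len(n_fill)))
  unknown <- setdiff(names(scn$effects), mets)
  if (length(unknown)) {
    stop(sprintf("effect names a metabolite absent from the panel: '%s'",
                 unknown[1]))
  }
  n <- scn$n_treated + scn$n_control
  with_seed(seed, {
    # abundance layout: named (signature-eligible) metabolites sit in the
    # low tail so the total-sum denominator is dominated by the filler panel
    med <- c(10^stats::runif(length(named), 3.8, 4.8),
             if (n_fill) 10^(seq(3.4, 6.7, length.out = n_fill) +
                               stats::runif(n_fill, -0.1, 0.1)))
    names(med) <- mets
    sdlog <- sqrt(log(1 + scn$noise_cv^2))
    X <- matrix(rep(med, each = n), n, n_metabolites,
                dimnames = list(c(sprintf("treated_%02d", seq_len(scn$n_treated)),
                                  sprintf("control_%02d", seq_len(scn$n_control))),
                                mets))
    X <- X * exp(matrix(stats::rnorm(n * n_metabolites, -sdlog^2 / 2, sdlog),
                        n, n_metabolites))
    # planted effects on treated samples, before the size factor
    if (length(scn$effects)) {
      idx <- match(names(scn$effects), mets)
      X[seq_len(scn$n_treated), idx] <-
        X[seq_len(scn$n_treated), idx, drop = FALSE] * rep(scn$effects, each = scn$n_treated)
    }
    # per-sample size factor (loading/injection), CV ~ 10%
    sf <- exp(stats::rnorm(n, 0, sqrt(log(1 + 0.1^2))))
    X <- X * sf
    # outliers: composition-distorting failure on a random half of the panel
    is_out <- stats::runif(n) < scn$outlier_rate
    for (i in which(is_out)) {
      hit <- sample.int(n_metabolites, floor(n_metabolites / 2))
      X[i, hit] <- X[i, hit] * 5
    }
    # spiked instrument control: fixed concentration, instrument noise only
    olo <- 1e5 * exp(stats::rnorm(n, 0, sqrt(log(1 + 0.01^2))))
    X <- cbind(X, olomoucine = olo)
    groups <- rep(c("treated", "control"), c(scn$n_treated, scn$n_control))
    altered <- scn$effects[scn$effects != 1]
    truth <- list(
      altered_metabolites = data.frame(
        metabolite = names(altered),
        direction = ifelse(altered > 1, "up", "down"),
        fold_change = unname(altered),
        stringsAsFactors = FALSE),
      outlier_samples = rownames(X)[is_out]
    )
    list(table = peak_table(X, groups, control_analyte = "olomoucine"),
         truth = truth)
  })
}

#' Generate a full inhibitor + knockout experiment set
#'
#' Emulates the signature-derivation design: three inhibitor experiments
#' (the main inhibitor first) plus one knockout experiment, all planting
#' the same transporter signature but with distinct sub-seeds.
#'
#' @param transporter `"pgp"`, `"bcrp"` or `"mrp2"`.
#' @param seed integer seed; sub-seeds are derived from it.
#' @param n_metabolites panel size, passed to [generate_peak_table()].
#' @return List of experiments; each has `table`, `truth` and `meta`
#'   (`compound`, `kind` = inhibitor/knockout, `main` flag, `sub_seed`).
#' @export
generate_experiment_set <- function(transporter, seed = 1, n_metabolites = 60) {
  if (!transporter %in% c("pgp", "bcrp", "mrp2")) {
    stop(sprintf("unknown transporter '%s'", transporter))
  }
  scns <- builtin_scenarios()
  inh <- scns[[paste0(transporter, "_inhibitor")]]
  ko <- scns[[paste0(transporter, "_ko")]]
  compounds <- switch(transporter,
    pgp = c("zosuquidar", "ritonavir", "valspodar"),
    bcrp = c("Ko143", "fumitremorgin C", "novobiocin"),
    mrp2 = c("MK571", "benzbromarone", "MK571 repeat"))
  out <- vector("list", 4)
  for (i in 1:3) {
    s <- seed * 1000L + i
    scn_i <- inh
    scn_i$compound <- compounds[i]
    g <- generate_peak_table(scn_i, n_metabolites, seed = s)
    out[[i]] <- c(g, list(meta = list(compound = compounds[i], kind = "inhibitor",
                                      main = i == 1L, sub_seed = s)))
  }
  s <- seed * 1000L + 4L
  g <- generate_peak_table(ko, n_metabolites, seed = s)
  out[[4]] <- c(g, list(meta = list(compound = ko$compound, kind = "knockout",
                                    main = FALSE, sub_seed = s)))
  out
}

#' Generate a synthetic transwell transport time series
#'
#' Receiver-compartment concentration rising linearly at the slope implied
#' by the true apparent permeability, `papp_true * area * c0 / vr`
#' (sink conditions), with multiplicative log-normal noise.
#'
#' @param papp_true true apparent permeability (cm/s).
#' @param c0 donor initial concentration (umol/L).
#' @param vr receiver volume (mL).
#' @param area insert area (cm2).
#' @param n_timepoints number of samples (>= 3), evenly spaced on
#'   `[0, t_max]`.
#' @param t_max assay duration (s).
#' @param noise_cv multiplicative noise CV on nonzero concentrations.
#' @param seed integer seed.
#' @param direction `"AtoB"` or `"BtoA"`.
#' @return A [transport_series()].
#' @export
generate_transport_series <- function(papp_true, c0 = 10, vr = 0.3, area = 0.11,
                                      n_timepoints = 5, t_max = 7200,
                                      noise_cv = 0, seed = 1,
                                      direction = c("AtoB", "BtoA")) {
  direction <- match.arg(direction)
  if (papp_true < 0) stop("papp_true must be >= 0")
  if (c0 <= 0 || vr <= 0 || area <= 0) stop("assay geometry must be positive")
  if (n_timepoints < 3) stop("need at least 3 time points")
  times <- seq(0, t_max, length.out = n_timepoints)
  slope <- papp_true * area * c0 / vr  # umol/L/s
  conc <- slope * times
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- with_seed(seed, conc * exp(stats::rnorm(n_timepoints, -sdlog^2 / 2, sdlog)))
  }
  transport_series(times, conc, c0 = c0, vr = vr, area = area,
                   direction = direction)
}
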