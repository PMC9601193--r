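# Shared fixture builders; everything is generated in code at test time.

# effect-free peak table with log-normal areas around 1e5
null_table <- function(seed, n = 12, p = 20, groups = rep(c("treated", "control"), each = n / 2)) {
  set.seed(seed)
  X <- matrix(exp(rnorm(n * p, log(1e5), 0.3)), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("m", seq_len(p))))
  peak_table(X, groups)
}

# tiny 2-group table with hand-set areas (2 samples per group)
tiny_table <- function(areas, groups = c("treated", "treated", "control", "control")) {
  peak_table(areas, groups)
}

# independent enumeration oracle for the two-sided exact Mann-Whitney p:
# U for 'a' counts pairs a > b; p doubles the smaller tail, capped at 1
mw_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  pool <- c(a, b)
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, function(idx) u_of(pool[idx], pool[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# one-component NIPALS PLS oracle on unit-variance scaled data (independent
# of the package's internals): returns scores and predicted y
pls1_oracle <- function(X, y_num) {
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  yc <- y_num - mean(y_num)
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(Xs %*% w)
  c1 <- sum(yc * t1) / sum(t1^2)
  list(scores = t1, y_hat = t1 * c1 + mean(y_num))
}

# run the signature-derivation pipeline on one generated experiment set
derive_from_set <- function(es, vip_threshold = 0.75) {
  exps <- lapply(es, function(e) {
    a <- analyze_experiment(e$table)
    list(changes = a$changes, vip = a$vip, kind = e$meta$kind,
         compound = e$meta$compound)
  })
  derive_signature(exps, vip_threshold = vip_threshold)
}

# score one scenario realization against the packaged signatures
scenario_scores <- function(scn, seed, n_metabolites = 60) {
  sim <- generate_peak_table(scn, n_metabolites = n_metabolites, seed = seed)
  pc <- percent_change_table(total_sum_normalize(sim$table))
  sigs <- reference_signatures()
  vapply(c(pgp = "pgp", mrp2 = "mrp2", bcrp = "bcrp"),
         function(tr) as.numeric(inhibition_score(pc, sigs[[tr]])), numeric(1))
}
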