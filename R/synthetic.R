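# Synthetic small/big molecule solubility sets with the statistical
# structure the analysis assumes: descriptor marginals centered on the
# training-database values, a shared latent size factor correlating the
# Abraham descriptors with molecular weight, heteroscedastic measurement
# SDs, and log S0 generated from a chosen true model plus noise.

#' Configuration for the synthetic-data generator
#'
#' @param n_compounds number of compounds to generate.
#' @param seed integer seed; every draw category uses its own stream
#'   derived from it, so adding a field never perturbs earlier draws and
#'   a fixed seed gives byte-identical tables.
#' @param model generating model: `"gse"`, `"absolv"` (linear Abraham)
#'   or `"absolv_bz"` (Abraham plus a nonlinear `B^z` term).
#' @param true_coefficients generating coefficient vector; `NULL` uses
#'   the model's preset — classic GSE `(0.5, -0.01, -1)` for small sets,
#'   big-molecule GSE `(-1.77, -0.01, -0.4)` for big sets, and the
#'   [absolv_2020()] vector for the Abraham models.
#' @param noise_sd mean measurement-error SD in log units (default 0.5,
#'   the typical interlaboratory reproducibility of solubility data).
#'   Per-entry error SDs are proportional to the entry's reported SD;
#'   `noise_sd = 0` gives noiseless data.
#' @param sd_range range (low, high) of the simulated *reported*
#'   measurement SDs, drawn uniformly (default 0.05-0.7 log).
#' @param z_true exponent of the generating `B^z` term
#'   (`"absolv_bz"` only; must be > 0).
#' @param c_bz coefficient of the generating `B^z` term (default 1).
#' @param marginals named list overriding the marginal targets: any of
#'   `clogp_mean`, `clogp_sd`, `mw_meanlog`, `mw_sdlog`, `mp_mean`,
#'   `mp_sd`, `nrot_max`.
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_compounds, seed = 1,
                             model = c("gse", "absolv", "absolv_bz"),
                             true_coefficients = NULL, noise_sd = 0.5,
                             sd_range = c(0.05, 0.7), z_true = NULL,
                             c_bz = 1, marginals = list()) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(sd_range) != 2 || sd_range[1] > sd_range[2] || sd_range[1] < 0) {
    stop("sd_range must be (low, high) with 0 <= low <= high")
  }
  if (model == "absolv_bz") {
    if (is.null(z_true)) stop("absolv_bz model requires z_true")
    if (z_true <= 0) stop("z_true must be > 0")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed), model = model,
                 true_coefficients = true_coefficients,
                 noise_sd = noise_sd, sd_range = sd_range,
                 z_true = z_true, c_bz = c_bz, marginals = marginals),
            class = "generator_config")
}

# truncated normal via inverse-CDF so each stream uses exactly n uniforms
rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

default_marginals <- function(big) {
  if (big) {
    list(clogp_mean = 3.17, clogp_sd = 1.8, mw_meanlog = log(1000),
         mw_sdlog = 0.25, mp_mean = 180, mp_sd = 45, nrot_max = 53)
  } else {
    list(clogp_mean = 1.89, clogp_sd = 1.8, mw_meanlog = log(265),
         mw_sdlog = 0.35, mp_mean = 135, mp_sd = 45, nrot_max = 20)
  }
}

generator_truth <- function(config, big) {
  switch(config$model,
    gse = if (!is.null(config$true_coefficients)) config$true_coefficients
          else if (big) c(-1.77, -0.01, -0.4) else c(0.5, -0.01, -1),
    {
      a <- absolv_2020()
      cf <- if (!is.null(config$true_coefficients)) config$true_coefficients
            else c(a$c0, a$c_a, a$c_b, a$c_s, a$c_e, a$c_v, a$c_ab)
      if (config$model == "absolv_bz") c(cf, config$c_bz) else cf
    })
}

generate_set <- function(config, big) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_compounds
  truth <- generator_truth(config, big)
  n_params <- length(truth)
  if (n < n_params + 2) {
    stop("under-determined: n_compounds must be at least ", n_params + 2,
         " for the ", config$model, " generating model")
  }
  m <- utils::modifyList(default_marginals(big), config$marginals)
  seed <- config$seed

  # one named stream per draw category
  set.seed(seed + 1L)
  mw <- exp(rtruncnorm(n, m$mw_meanlog, m$mw_sdlog,
                       if (big) log(800) else log(100),
                       if (big) log(2400) else log(799)))
  size <- mw / 280
  set.seed(seed + 2L)
  mp <- rtruncnorm(n, m$mp_mean, m$mp_sd, 40, 350)
  set.seed(seed + 3L)
  clogp <- rtruncnorm(n, m$clogp_mean, m$clogp_sd, -4, 9)
  set.seed(seed + 4L)
  A <- rgamma(n, shape = 1.5, scale = pmax(0.5 * size, 0.05) / 1.5)
  B <- rgamma(n, shape = 4, scale = 1.3 * pmax(size, 0.2) / 4)
  S_pi <- rgamma(n, shape = 4, scale = 1.6 * pmax(size, 0.2) / 4)
  E <- rgamma(n, shape = 4, scale = 1.1 * pmax(size, 0.2) / 4)
  V <- pmax(mw / 130 + rnorm(n, 0, 0.15), 0.3)
  set.seed(seed + 5L)
  nrot <- if (big) {
    3L + rbinom_int(n, m$nrot_max - 3L)
  } else {
    rpois(n, 5)
  }
  set.seed(seed + 6L)
  sd_i <- runif(n, config$sd_range[1], config$sd_range[2])
  mean_sd <- mean(config$sd_range)
  err_scale <- if (mean_sd > 0) config$noise_sd / mean_sd else 0
  set.seed(seed + 7L)
  eps <- rnorm(n, 0, sd_i * err_scale)

  mu <- if (config$model == "gse") {
    truth[1] + truth[2] * (mp - 25) + truth[3] * clogp
  } else {
    base <- drop(cbind(1, A, B, S_pi, E, V, A * B) %*% truth[1:7])
    if (config$model == "absolv_bz") {
      base + truth[8] * pow_b(B, config$z_true)
    } else {
      base
    }
  }

  out <- data.frame(
    id = sprintf("%s%05d", if (big) "big" else "sml", seq_len(n)),
    name = sprintf("synthetic %s molecule %d",
                   if (big) "big" else "small", seq_len(n)),
    log_s0 = mu + eps, sd = sd_i, mw = mw, mp = mp, clogp = clogp,
    nha = as.integer(round(2.2 * B)), nhd = as.integer(round(1.8 * A)),
    nrot = as.integer(nrot), A = A, B = B, S_pi = S_pi, E = E, V = V,
    ionization = "neutral", temperature = 298.15,
    stringsAsFactors = FALSE
  )
  out <- as_compound_table(out)
  attr(out, "true_coefficients") <- truth
  attr(out, "config") <- config
  out
}

# uniform integer draw on 0..k via a single runif stream
rbinom_int <- function(n, k) as.integer(floor(runif(n) * (k + 1L)))

#' Generate a synthetic small-molecule solubility set
#'
#' Emulates the statistical structure of a small-molecule intrinsic
#' solubility training database: molecular weights below 800 Da
#' (lognormal around 280 Da), melting points from a truncated normal on
#' 40-350 degrees C, clogP centered on 1.89, positive Abraham
#' descriptors correlated with a latent size factor, heteroscedastic
#' reported SDs, and log S0 from the configured true model plus noise.
#'
#' @param config a [generator_config()].
#' @return a `compound_table` with attributes `true_coefficients` and
#'   `config`.
#' @export
generate_small_set <- function(config) generate_set(config, big = FALSE)

#' Generate a synthetic big-molecule solubility set
#'
#' As [generate_small_set()] but with molecular weights >= 800 Da,
#' descriptors scaled up through the latent size factor, wide
#' rotatable-bond counts (3 up to `nrot_max`, default 53), and the
#' big-molecule GSE `(-1.77, -0.01, -0.4)` as the default generating
#' model.
#'
#' @param config a [generator_config()].
#' @return a `compound_table`.
#' @export
generate_big_set <- function(config) generate_set(config, big = TRUE)

#' Generate a set with a nonlinear B^z contribution
#'
#' Small-molecule set whose generating model adds `c_bz * B^z_true` to
#' the linear Abraham model — the ground truth for exponent-scan
#' recovery experiments. With `z_true = 1`, the set is in expectation a
#' linear Abraham set with a merged B coefficient.
#'
#' @param config a [generator_config()] with `model = "absolv_bz"` and
#'   `z_true` set.
#' @return a `compound_table`.
#' @export
generate_bz_set <- function(config) {
  if (config$model != "absolv_bz") {
    stop("generate_bz_set requires a config with model = 'absolv_bz'")
  }
  generate_set(config, big = FALSE)
}
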