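#' Synthetic trade worlds with gravity-model structure
#'
#' Generates bilateral flow and indicator tables with the statistical
#' features the analysis assumes: Pareto (heavy-tailed) country masses so
#' the thresholded network is scale-free-like, gravity flows
#' G * S_i^alpha * S_j^beta / d_ij^gamma with log-normal noise, GDP scaled
#' so imports/GDP sits near the few-percent range of real agricultural
#' dependence, and an epidemic-risk index that is identically 1 in the
#' pre-epidemic regime and log-normally dispersed in the epidemic regime.
#'
#' @name synthetic_world
NULL

#' Configuration for a synthetic trade world
#'
#' @param n_countries number of countries (>= 3); default 88, the sample
#'   size of the published network.
#' @param size_exponent Pareto tail index for country economic mass;
#'   <= 2 gives the heavy tail behind scale-free-like degree structure.
#' @param gravity numeric c(alpha, beta, gamma): exporter-mass and
#'   importer-mass elasticities and the distance-decay exponent.
#' @param noise_sd sd of the log-scale flow noise.
#' @param total_trade grand total of all flows, USD (flows are rescaled to
#'   it); default 3e11, the scale of the observed yearly totals.
#' @param gdp_ratio total GDP as a multiple of total trade; 20 puts median
#'   imports/GDP near 0.05, i.e. EDI + 1 near 1.05.
#' @param cri_regime `"pre_epidemic"` (CRI identically 1) or `"epidemic"`
#'   (log-normal CRI).
#' @param cri_meanlog,cri_sdlog epidemic CRI log-normal parameters;
#'   defaults give supplier CRIs mostly in 20-150.
#' @param threshold USD binarization threshold recorded with the world.
#' @param seed integer RNG seed.
#' @return a `world_config` list.
#' @export
world_config <- function(n_countries = 88L,
                         size_exponent = 1.5,
                         gravity = c(alpha = 1, beta = 1, gamma = 1),
                         noise_sd = 0.3,
                         total_trade = 3e11,
                         gdp_ratio = 20,
                         cri_regime = c("pre_epidemic", "epidemic"),
                         cri_meanlog = log(60),
                         cri_sdlog = 0.5,
                         threshold = 1e8,
                         seed = 1L) {
  cri_regime <- match.arg(cri_regime)
  if (n_countries < 3L) stop("world_config: n_countries must be >= 3",
                             call. = FALSE)
  scales <- c(size_exponent, noise_sd, total_trade, gdp_ratio, threshold)
  if (any(scales <= 0) && threshold != 0) {
    if (any(c(size_exponent, total_trade, gdp_ratio) <= 0) || noise_sd < 0)
      stop("world_config: scale parameters must be positive", call. = FALSE)
  }
  structure(list(n_countries = as.integer(n_countries),
                 size_exponent = size_exponent,
                 gravity = stats::setNames(as.numeric(gravity),
                                           c("alpha", "beta", "gamma")),
                 noise_sd = noise_sd,
                 total_trade = total_trade,
                 gdp_ratio = gdp_ratio,
                 cri_regime = cri_regime,
                 cri_meanlog = cri_meanlog,
                 cri_sdlog = cri_sdlog,
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "world_config")
}

.synth_codes <- function(n) {
  # synthetic ISO3-like codes: XAA, XAB, ... (clearly not real countries)
  stopifnot(n <= 26 * 26)
  first <- rep(LETTERS, each = 26)[seq_len(n)]
  second <- rep(LETTERS, times = 26)[seq_len(n)]
  paste0("X", first, second)
}

#' Generate a synthetic trade world
#'
#' Fully reproducible from the config seed: masses S ~ Pareto, planar
#' coordinates -> Euclidean distances, gravity flows with log-normal noise
#' rescaled to the configured total, GDP proportional to mass and scaled by
#' `gdp_ratio`, CRI per regime.
#'
#' @param config a [world_config()].
#' @param year calendar year stamped on the tables.
#' @return list: `flows` (a `trade_flows`), `indicators`
#'   (`iso3,year,gdp_usd,cri`), `truth` (masses, coordinates, distances —
#'   for parameter-recovery checks), `config`.
#' @export
generate_world <- function(config, year = 2019L) {
  stopifnot(inherits(config, "world_config"))
  n <- config$n_countries
  with_seed(config$seed, {
    codes <- .synth_codes(n)
    # Pareto(xm = 1, alpha): xm * U^(-1/alpha)
    s <- stats::runif(n)^(-1 / config$size_exponent)
    xy <- cbind(stats::runif(n), stats::runif(n))
    d <- as.matrix(stats::dist(xy))
    d <- pmax(d, 0.01)  # floor so co-located pairs stay finite
    al <- config$gravity[["alpha"]]
    be <- config$gravity[["beta"]]
    ga <- config$gravity[["gamma"]]
    raw <- outer(s^al, s^be) / d^ga
    diag(raw) <- 0
    eps <- matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
    diag(eps) <- 0
    w <- raw * exp(eps)
    w <- w / sum(w) * config$total_trade
    dimnames(w) <- list(codes, codes)

    idx <- which(diag(n) == 0, arr.ind = TRUE)
    flows_df <- data.frame(year = as.integer(year),
                           exporter = codes[idx[, 1]],
                           importer = codes[idx[, 2]],
                           value = w[idx],
                           stringsAsFactors = FALSE)
    gdp <- config$gdp_ratio * config$total_trade * s / sum(s)
    cri <- if (config$cri_regime == "pre_epidemic") {
      rep(1, n)
    } else {
      stats::rlnorm(n, config$cri_meanlog, config$cri_sdlog)
    }
    list(flows = trade_flows(flows_df),
         indicators = data.frame(iso3 = codes, year = as.integer(year),
                                 gdp_usd = gdp, cri = cri,
                                 stringsAsFactors = FALSE),
         truth = list(mass = stats::setNames(s, codes), coords = xy,
                      dist = d),
         config = config)
  })
}

#' Find a binarization threshold achieving a target network density
#'
#' Binary search over the observed flow values so the thresholded directed
#' density lands within 10% of the target.
#'
#' @param flows a `trade_flows` object.
#' @param year calendar year.
#' @param target_density desired density in (0, 1).
#' @param tol relative tolerance (default 0.10).
#' @return the threshold in USD, with attribute `achieved_density`.
#' @export
calibrate_threshold <- function(flows, year, target_density, tol = 0.10) {
  if (!is.numeric(target_density) || target_density <= 0 ||
      target_density >= 1) {
    stop("calibrate_threshold: target_density must be in (0, 1)",
         call. = FALSE)
  }
  net <- build_network(flows, year)
  n <- length(net$nodes)
  pairs <- n * (n - 1)
  v <- sort(net$weights[net$weights > 0], decreasing = TRUE)
  dens_at <- function(tau) sum(v >= tau) / pairs
  d_max <- length(v) / pairs           # tau -> 0+
  d_min <- 1 / pairs                   # tau = max value
  lo_ok <- target_density * (1 - tol)
  hi_ok <- target_density * (1 + tol)
  if (d_max < lo_ok || d_min > hi_ok) {
    stop(sprintf(paste0("calibrate_threshold: target %.4g unattainable; ",
                        "attainable density range is [%.4g, %.4g]"),
                 target_density, d_min, d_max), call. = FALSE)
  }
  lo <- min(v) / 2; hi <- max(v) * 2
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    d <- dens_at(mid)
    if (d >= lo_ok && d <= hi_ok) {
      return(structure(mid, achieved_density = d))
    }
    if (d > target_density) lo <- mid else hi <- mid
  }
  # step function: fall back to the exact order statistic
  e_target <- max(1L, round(target_density * pairs))
  tau <- v[min(e_target, length(v))]
  structure(tau, achieved_density = dens_at(tau))
}
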