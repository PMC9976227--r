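#' Network-level metrics: density, degrees, trade shares, degree-distribution fit
#' @name network_metrics
NULL

#' Directed network density
#'
#' Density of the binarized network: present directed edges over the
#' n(n-1) possible ones (no self-loops).
#'
#' @param net a binarized `trade_network`, or a single integer edge count
#'   when `n` is given directly.
#' @param n number of nodes, only when `net` is an edge count.
#' @return the density in `[0, 1]`.
#' @export
network_density <- function(net, n = NULL) {
  if (inherits(net, "trade_network")) {
    if (is.null(net$binary)) {
      stop("network_density: binarize the network first", call. = FALSE)
    }
    e <- sum(net$binary)
    n <- length(net$nodes)
  } else {
    e <- as.numeric(net)
    if (is.null(n)) stop("network_density: n required with an edge count",
                         call. = FALSE)
  }
  if (n < 2) stop("network_density: undefined for fewer than 2 nodes",
                  call. = FALSE)
  e / (n * (n - 1))
}

#' Degree table of a binarized trade network
#'
#' Out-degree is the row sum (countries supplied), in-degree the column sum
#' (suppliers). `degree` counts each directed edge once per endpoint, so
#' it is in-degree + out-degree.
#'
#' @param net a binarized `trade_network`.
#' @return data frame: `node`, `out_degree`, `in_degree`, `degree`.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  if (is.null(net$binary)) {
    stop("degrees: binarize the network first", call. = FALSE)
  }
  data.frame(node = net$nodes,
             out_degree = unname(rowSums(net$binary)),
             in_degree = unname(colSums(net$binary)),
             degree = unname(rowSums(net$binary) + colSums(net$binary)),
             stringsAsFactors = FALSE)
}

#' Country trade shares and top-k cumulative concentration
#'
#' Per-country export or import totals for one year, as shares of the grand
#' total of all flows that year (the convention behind "proportion of total
#' trade" tables). Rank ties are broken by country code.
#'
#' @param flows a `trade_flows` object.
#' @param year calendar year.
#' @param direction `"export"` (totals by exporter) or `"import"`.
#' @param top_k how many top countries enter the cumulative figure.
#' @return data frame `country`, `flow_total`, `share`, `rank`,
#'   `cumulative_top_k`, ordered by rank; attributes `grand_total`,
#'   `top_k`, `cumulative_top_k`.
#' @export
trade_shares <- function(flows, year, direction = c("export", "import"),
                         top_k = 10L) {
  direction <- match.arg(direction)
  fy <- flows[flows$year == year, , drop = FALSE]
  if (nrow(fy) == 0L) stop("trade_shares: no flows for year ", year,
                           call. = FALSE)
  grand <- sum(fy$value)
  if (grand <= 0) stop("trade_shares: grand total is zero for year ", year,
                       call. = FALSE)
  key <- if (direction == "export") fy$exporter else fy$importer
  totals <- tapply(fy$value, key, sum)
  out <- data.frame(country = names(totals),
                    flow_total = as.numeric(totals),
                    stringsAsFactors = FALSE)
  out$share <- out$flow_total / grand
  out <- out[order(-out$share, out$country), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$cumulative_top_k <- cumsum(out$share)
  rownames(out) <- NULL
  k <- min(top_k, nrow(out))
  structure(out,
            grand_total = grand,
            top_k = k,
            cumulative_top_k = out$cumulative_top_k[k])
}

#' Fit an exponential decay to an empirical degree distribution
#'
#' The empirical probability p(k) = (#nodes with degree k) / n over the
#' observed degree values is fitted by a * exp(-b * k), by least squares on
#' the raw probabilities (robust to zero-probability bins; the log-linear
#' fit is available via `method`). With exactly two distinct degrees the
#' two-parameter model is saturated and solved exactly.
#'
#' @param deg a degree table from [degrees()], or a numeric degree vector.
#' @param which which column to use: `"degree"`, `"in"`, or `"out"`.
#' @param method `"nls"` (least squares on probabilities, default) or
#'   `"loglinear"` (linear regression on log p).
#' @return list of class `exp_fit`: `amplitude` (a), `rate` (b), `rmse`,
#'   plus the `support` data frame of (k, p) pairs used.
#' @export
fit_exponential_distribution <- function(deg, which = c("degree", "in", "out"),
                                         method = c("nls", "loglinear")) {
  which <- match.arg(which)
  method <- match.arg(method)
  d <- if (is.data.frame(deg)) {
    switch(which, degree = deg$degree, "in" = deg$in_degree,
           "out" = deg$out_degree)
  } else {
    as.numeric(deg)
  }
  n <- length(d)
  tab <- table(d)
  k <- as.numeric(names(tab))
  p <- as.numeric(tab) / n
  if (length(k) < 2L) {
    stop("fit_exponential_distribution: need at least 2 distinct degree values",
         call. = FALSE)
  }

  if (length(k) == 2L) {
    # saturated: solve a e^{-b k1} = p1, a e^{-b k2} = p2 exactly
    b <- (log(p[1]) - log(p[2])) / (k[2] - k[1])
    a <- p[1] * exp(b * k[1])
    return(structure(list(amplitude = a, rate = b, rmse = 0,
                          support = data.frame(k = k, p = p)),
                     class = "exp_fit"))
  }

  pos <- p > 0
  start_fit <- stats::lm(log(p[pos]) ~ k[pos])
  a0 <- exp(unname(stats::coef(start_fit)[1]))
  b0 <- -unname(stats::coef(start_fit)[2])

  if (method == "loglinear") {
    fitted <- a0 * exp(-b0 * k)
    return(structure(list(amplitude = a0, rate = b0,
                          rmse = sqrt(mean((p - fitted)^2)),
                          support = data.frame(k = k, p = p)),
                     class = "exp_fit"))
  }

  obj <- function(par) sum((p - par[1] * exp(-par[2] * k))^2)
  opt <- stats::optim(c(a0, b0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  a <- opt$par[1]; b <- opt$par[2]
  structure(list(amplitude = a, rate = b,
                 rmse = sqrt(opt$value / length(k)),
                 support = data.frame(k = k, p = p)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> p(k) ~ %.4g * exp(-%.4g k), rmse %.3g over %d bins\n",
              x$amplitude, x$rate, x$rmse, nrow(x$support)))
  invisible(x)
}

#' One-line JSON-ready network summary
#'
#' @param net a binarized `trade_network`.
#' @return list `year`, `n`, `E`, `density` (density at 3 decimals is the
#'   reporting convention; the raw value is returned).
#' @export
network_summary <- function(net) {
  list(year = net$year,
       n = length(net$nodes),
       E = sum(net$binary),
       density = network_density(net),
       threshold = net$threshold)
}
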