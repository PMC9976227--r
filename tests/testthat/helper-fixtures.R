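# shared fixtures and independent oracles for the suite

# build a trade_flows table from an edge list (matrix or data.frame with
# exporter, importer, value columns), one year
flows_from_edges <- function(edges, year = 2019, value = 2e8) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2L) edges$value <- value
  names(edges) <- c("exporter", "importer", "value")
  trade_flows(data.frame(year = year, edges, stringsAsFactors = FALSE))
}

# binarized network from an undirected edge list on integer node ids;
# width-3 codes so lexicographic node order equals numeric order up to 999
net_from_undirected <- function(el, n, year = 1L) {
  codes <- sprintf("N%03d", seq_len(n))
  f <- flows_from_edges(data.frame(exporter = codes[el[, 1]],
                                   importer = codes[el[, 2]]), year = year)
  binarize(build_network(f, year, countries = codes), 1e8)
}

# Erdos-Renyi undirected edge list (at least one edge guaranteed)
random_undirected_edges <- function(n, p = 0.5) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  pairs[keep, , drop = FALSE]
}

# exhaustive-enumeration oracle for optimal k-class 1-D classification:
# minimal within-class SS over all contiguous partitions of the sorted data
enumerate_breaks_oracle <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  best <- list(wss = Inf, starts = NULL)
  cuts <- combn(2:n, k - 1)
  for (ci in seq_len(ncol(cuts))) {
    starts <- c(1L, cuts[, ci])
    ends <- c(starts[-1L] - 1L, n)
    w <- sum(vapply(seq_len(k),
                    function(c) ssd(v[starts[c]:ends[c]]), numeric(1)))
    if (w < best$wss - 1e-12) best <- list(wss = w, starts = starts)
  }
  classes <- rep(seq_len(k), times = diff(c(best$starts, n + 1L)))
  list(wss = best$wss, classes = classes, sorted = v)
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# the published top-10 trade table: printed quantities, printed proportions,
# and printed grand totals for both years and both directions
table3_fixture <- function() {
  list(
    export_2019 = data.frame(
      country = c("CHN", "IDN", "IND", "THA", "RUS", "UKR", "ITA", "MYS",
                  "NZL", "POL"),
      quantity = c(28388004154, 23753536126, 20098378587, 18712887461,
                   17104700703, 15917418319, 15751194738, 14731175035,
                   14702055772, 12968594457),
      printed_pct = c(9.24, 7.73, 6.54, 6.09, 5.56, 5.18, 5.12, 4.79,
                      4.78, 4.22),
      stringsAsFactors = FALSE),
    export_2021 = data.frame(
      country = c("IDN", "CHN", "IND", "THA", "RUS", "MYS", "UKR", "ITA",
                  "NZL", "POL"),
      quantity = c(35888649919, 28794103903, 26770803485, 23689595579,
                   22983726395, 21401527961, 20716309523, 17911740180,
                   17307137156, 15300714747),
      printed_pct = c(9.41, 7.55, 7.02, 6.21, 6.02, 5.61, 5.43, 4.69,
                      4.54, 4.01),
      stringsAsFactors = FALSE),
    import_2021_chn = list(quantity = 78552306715, printed_pct = 20.6),
    grand_total = c(`2019` = 307384908993, `2021` = 381582788232),
    cumulative_top10_export = c(`2019` = 59.25, `2021` = 60.49)
  )
}

# flows table realizing one year's export rows: each listed exporter ships
# its printed quantity to a sink importer, and the remainder of the grand
# total is spread over 40 small filler exporters (each below the 10th rank)
table3_flows <- function(year) {
  t3 <- table3_fixture()
  rows <- t3[[paste0("export_", year)]]
  remainder <- t3$grand_total[[as.character(year)]] - sum(rows$quantity)
  fillers <- sprintf("Z%02d", seq_len(40))
  df <- data.frame(
    year = year,
    exporter = c(rows$country, fillers),
    importer = "SNK",
    value = c(rows$quantity, rep(remainder / 40, 40)),
    stringsAsFactors = FALSE)
  trade_flows(df)
}
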