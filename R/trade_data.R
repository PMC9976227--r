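#' Bilateral trade flows and directed trade networks
#'
#' A `trade_flows` object is a validated long-format table of bilateral
#' flows (one row per year x exporter x importer, value in USD). A
#' `trade_network` is the per-year directed matrix view: rows are exporters,
#' columns are importers, so an edge i -> j reads "i supplies j" and the
#' in-degree of a country counts its above-threshold suppliers.
#'
#' @name trade_data
NULL

.default_column_map <- c(
  year     = "year",
  exporter = "exporter_iso3",
  importer = "importer_iso3",
  value    = "value_usd"
)

#' Construct a validated trade-flow table
#'
#' Validates and aggregates an in-memory data frame of bilateral flows.
#' Rows with negative values or with exporter == importer are rejected and
#' logged in the validation report; duplicate (year, exporter, importer)
#' rows are summed.
#'
#' @param df data frame with columns `year`, `exporter`, `importer`, `value`.
#' @param known_codes optional character vector of recognised ISO3 codes;
#'   unknown codes are kept but flagged in the report.
#' @return a `trade_flows` data frame with a `validation` attribute listing
#'   `rows_in`, `rows_out`, and a `rejected` data frame of dropped rows with
#'   reasons.
#' @export
trade_flows <- function(df, known_codes = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("year", "exporter", "importer", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("trade_flows: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df$year <- as.integer(df$year)
  df$exporter <- toupper(as.character(df$exporter))
  df$importer <- toupper(as.character(df$importer))
  df$value <- as.numeric(df$value)

  rows_in <- nrow(df)
  reason <- rep(NA_character_, rows_in)
  reason[is.na(df$value) | is.na(df$year)] <- "missing value"
  reason[is.na(reason) & df$value < 0] <- "negative value"
  reason[is.na(reason) & df$exporter == df$importer] <- "self-flow"

  rejected <- df[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  keep <- df[is.na(reason), , drop = FALSE]

  if (nrow(keep) > 0L) {
    agg <- stats::aggregate(value ~ year + exporter + importer,
                            data = keep, FUN = sum)
    agg <- agg[order(agg$year, agg$exporter, agg$importer), , drop = FALSE]
  } else {
    agg <- keep
  }
  rownames(agg) <- NULL

  flagged <- character(0)
  if (!is.null(known_codes)) {
    codes <- unique(c(agg$exporter, agg$importer))
    flagged <- sort(setdiff(codes, toupper(known_codes)))
  }

  structure(agg,
            class = c("trade_flows", "data.frame"),
            validation = list(rows_in = rows_in,
                              rows_out = nrow(agg),
                              rejected = rejected,
                              unknown_codes = flagged))
}

#' Read bilateral trade flows from a long-format CSV
#'
#' @param path CSV file path (UTF-8, header required, "." decimal).
#' @param column_map named character vector mapping the canonical names
#'   `year`, `exporter`, `importer`, `value` to the file's column names.
#'   Defaults to `year,exporter_iso3,importer_iso3,value_usd`.
#' @param known_codes optional recognised ISO3 codes (see [trade_flows()]).
#' @return a `trade_flows` object; the validation report is in
#'   `attr(x, "validation")`.
#' @export
load_trade_flows <- function(path, column_map = .default_column_map,
                             known_codes = NULL) {
  if (!file.exists(path)) stop("load_trade_flows: no such file: ", path,
                               call. = FALSE)
  cmap <- .default_column_map
  cmap[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols) > 0L) {
    stop("load_trade_flows: columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(year = raw[[cmap[["year"]]]],
                   exporter = raw[[cmap[["exporter"]]]],
                   importer = raw[[cmap[["importer"]]]],
                   value = raw[[cmap[["value"]]]],
                   stringsAsFactors = FALSE)
  trade_flows(df, known_codes = known_codes)
}

#' Read a per-country indicator table (GDP and epidemic risk index)
#'
#' @param path CSV with columns `iso3,year,gdp_usd,cri`.
#' @return data frame with those columns, codes upper-cased.
#' @export
load_indicators <- function(path) {
  if (!file.exists(path)) stop("load_indicators: no such file: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("iso3", "year", "gdp_usd", "cri")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("load_indicators: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$iso3 <- toupper(as.character(raw$iso3))
  raw$year <- as.integer(raw$year)
  raw[need]
}

#' Build the directed weighted trade network for one year
#'
#' @param flows a `trade_flows` object.
#' @param year calendar year to extract.
#' @param countries optional country list; the matrix is restricted to it
#'   (absent pairs become 0). Defaults to all countries trading that year.
#' @return a `trade_network`: list with `year`, `nodes` (sorted codes),
#'   `weights` (n x n USD matrix, rows = exporters, columns = importers,
#'   zero diagonal), and empty `binary`/`threshold` slots.
#' @export
build_network <- function(flows, year, countries = NULL) {
  stopifnot(inherits(flows, "trade_flows") || is.data.frame(flows))
  fy <- flows[flows$year == year, , drop = FALSE]
  if (nrow(fy) == 0L && is.null(countries)) {
    stop("build_network: no flows for year ", year, call. = FALSE)
  }
  nodes <- if (is.null(countries)) {
    sort(unique(c(fy$exporter, fy$importer)))
  } else {
    sort(unique(toupper(countries)))
  }
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  fy <- fy[fy$exporter %in% nodes & fy$importer %in% nodes, , drop = FALSE]
  if (nrow(fy) > 0L) {
    w[cbind(match(fy$exporter, nodes), match(fy$importer, nodes))] <- fy$value
  }
  diag(w) <- 0
  structure(list(year = as.integer(year), nodes = nodes, weights = w,
                 binary = NULL, threshold = NULL),
            class = "trade_network")
}

#' Binarize a trade network at a USD threshold
#'
#' An edge i -> j is present when the flow meets the threshold (inclusive,
#' so a flow of exactly the threshold counts). With `threshold = 0` edges
#' are exactly the positive-weight cells.
#'
#' @param net a `trade_network` with weights.
#' @param threshold USD cutoff, >= 0. The headline analysis uses 1e8
#'   (100 million USD).
#' @return the network with `binary` (0/1 matrix) and `threshold` filled in.
#' @export
binarize <- function(net, threshold = 1e8) {
  stopifnot(inherits(net, "trade_network"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("binarize: threshold must be a single non-negative number",
         call. = FALSE)
  }
  b <- (net$weights > 0 & net$weights >= threshold) + 0L
  diag(b) <- 0L
  net$binary <- b
  net$threshold <- threshold
  net
}

#' @export
print.trade_network <- function(x, ...) {
  n <- length(x$nodes)
  e <- if (is.null(x$binary)) sum(x$weights > 0) else sum(x$binary)
  cat(sprintf("<trade_network> year %d: %d countries, %d %s edges%s\n",
              x$year, n, e,
              if (is.null(x$binary)) "weighted" else "binary",
              if (is.null(x$threshold)) ""
              else sprintf(" (threshold %s USD)",
                           format(x$threshold, big.mark = ","))))
  invisible(x)
}

.net_edges <- function(net) {
  m <- if (!is.null(net$binary)) net$binary else (net$weights > 0) + 0L
  idx <- which(m != 0, arr.ind = TRUE)
  data.frame(source = net$nodes[idx[, 1L]],
             target = net$nodes[idx[, 2L]],
             weight = net$weights[idx],
             stringsAsFactors = FALSE)[order(net$nodes[idx[, 1L]],
                                             net$nodes[idx[, 2L]]), ,
                                       drop = FALSE]
}

#' Export a trade network to GEXF, GraphML, or an edge-list CSV
#'
#' Written files round-trip: [import_graph()] on the output recovers the
#' same node set and edge set.
#'
#' @param net a `trade_network`.
#' @param format one of `"gexf"`, `"graphml"`, `"edgelist"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, format = c("gexf", "graphml", "edgelist"),
                         path) {
  stopifnot(inherits(net, "trade_network"))
  format <- tolower(format)
  format <- match.arg(format)
  edges <- .net_edges(net)
  nodes <- net$nodes

  if (format == "edgelist") {
    utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }

  if (format == "gexf") {
    doc <- xml2::xml_new_root("gexf",
                              xmlns = "http://www.gexf.net/1.2draft",
                              version = "1.2")
    graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                                 defaultedgetype = "directed")
    nn <- xml2::xml_add_child(graph, "nodes")
    for (v in nodes) xml2::xml_add_child(nn, "node", id = v, label = v)
    ee <- xml2::xml_add_child(graph, "edges")
    if (nrow(edges) > 0L) {
      for (i in seq_len(nrow(edges))) {
        xml2::xml_add_child(ee, "edge", id = as.character(i - 1L),
                            source = edges$source[i],
                            target = edges$target[i],
                            weight = format(edges$weight[i], scientific = FALSE))
      }
    }
    xml2::write_xml(doc, path)
    return(invisible(path))
  }

  # graphml
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "w", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "directed")
  for (v in nodes) xml2::xml_add_child(graph, "node", id = v)
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      e <- xml2::xml_add_child(graph, "edge",
                               source = edges$source[i],
                               target = edges$target[i])
      d <- xml2::xml_add_child(e, "data", key = "w")
      xml2::xml_text(d) <- format(edges$weight[i], scientific = FALSE)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import a graph written by [export_graph()]
#'
#' @param path file path.
#' @param format one of `"gexf"`, `"graphml"`, `"edgelist"`.
#' @return list with `nodes` (character) and `edges`
#'   (source/target/weight data frame).
#' @export
import_graph <- function(path, format = c("gexf", "graphml", "edgelist")) {
  format <- tolower(format)
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(list(nodes = sort(unique(c(edges$source, edges$target))),
                edges = edges))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_xp <- if (format == "gexf") ".//g:node" else ".//g:node"
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, node_xp, ns), "id")
  enodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
  w <- if (format == "gexf") {
    as.numeric(xml2::xml_attr(enodes, "weight"))
  } else {
    as.numeric(xml2::xml_text(xml2::xml_find_first(enodes, "./g:data", ns)))
  }
  edges <- data.frame(source = xml2::xml_attr(enodes, "source"),
                      target = xml2::xml_attr(enodes, "target"),
                      weight = w, stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
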