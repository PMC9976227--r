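#' External supply risk: EDI, HHI, RICI, the AECSI composite, dominant type
#'
#' The composite scores an importing country's exposure to external
#' agricultural supply shocks from three components: external dependence
#' (imports over GDP, shifted by +1), import concentration
#' (Herfindahl-Hirschman over supplier shares), and epidemic exposure
#' (import-share-weighted supplier risk index). AECSI is their sum; the
#' component contributing more than half of it names the dominant risk
#' type, otherwise the country is a compound-risk case.
#'
#' @name risk_model
NULL

#' External dependence index (imports / GDP, +1 shift)
#'
#' e = imports / gdp; returns 1 when e is non-positive (the published
#' rule's floor; with positive GDP the ratio cannot actually be negative),
#' otherwise e + 1. Always >= 1. Vectorized.
#'
#' @param imports agricultural import value, USD, >= 0.
#' @param gdp GDP, USD, > 0.
#' @return r_edi, dimensionless >= 1.
#' @export
edi <- function(imports, gdp) {
  if (any(!is.finite(gdp)) || any(gdp <= 0)) {
    stop("edi: gdp must be positive", call. = FALSE)
  }
  if (any(!is.finite(imports)) || any(imports < 0)) {
    stop("edi: imports must be non-negative", call. = FALSE)
  }
  e <- imports / gdp
  ifelse(e <= 0, 1, e + 1)
}

.import_shares <- function(flows, importer, year) {
  fy <- flows[flows$year == year & flows$importer == importer &
                flows$value > 0, , drop = FALSE]
  if (nrow(fy) == 0L) return(NULL)
  tot <- sum(fy$value)
  sh <- tapply(fy$value, fy$exporter, sum) / tot
  sh
}

#' Herfindahl-Hirschman import-concentration index
#'
#' Sum of squared supplier shares of the importer's total imports; 1 for a
#' sole supplier, 1/K for K equal suppliers.
#'
#' @param flows a `trade_flows` object.
#' @param importer ISO3 code.
#' @param year calendar year.
#' @return r_hhi in (0, 1].
#' @export
hhi <- function(flows, importer, year) {
  sh <- .import_shares(flows, importer, year)
  if (is.null(sh)) {
    stop("hhi: ", importer, " has no positive imports in ", year,
         call. = FALSE)
  }
  sum(sh^2)
}

#' Epidemic-risk exposure index (RICI)
#'
#' Default `partner_cri` mode: the import-share-weighted mean of the
#' suppliers' risk indices, so exposure tracks where the imports come from.
#' The degenerate `own_cri` mode returns the importer's own index
#' regardless of shares (the literal reading of the formula, which
#' collapses because shares sum to one); it is kept as an option. In a
#' pre-epidemic year with every CRI = 1 both modes give exactly 1.
#'
#' @param flows a `trade_flows` object.
#' @param indicators data frame `iso3,year,gdp_usd,cri`.
#' @param importer ISO3 code.
#' @param year calendar year.
#' @param mode `"partner_cri"` (default) or `"own_cri"`.
#' @return r_rici >= 0; bounded by the min and max supplier CRI in
#'   partner mode.
#' @export
rici <- function(flows, indicators, importer, year,
                 mode = c("partner_cri", "own_cri")) {
  mode <- match.arg(mode)
  cri_of <- function(codes) {
    idx <- match(paste(codes, year), paste(indicators$iso3, indicators$year))
    cri <- indicators$cri[idx]
    if (any(is.na(cri))) {
      stop("rici: missing CRI for ", year, ": ",
           paste(codes[is.na(cri)], collapse = ", "), call. = FALSE)
    }
    cri
  }
  if (mode == "own_cri") return(cri_of(importer))
  sh <- .import_shares(flows, importer, year)
  if (is.null(sh)) {
    stop("rici: ", importer, " has no positive imports in ", year,
         call. = FALSE)
  }
  cri <- cri_of(names(sh))
  # shares sum to 1, so a common CRI value passes through exactly (the
  # pre-epidemic year, CRI identically 1, must give exactly 1)
  if (length(unique(cri)) == 1L) return(cri[[1L]])
  sum(sh * cri)
}

#' AECSI composite and component contribution rates
#'
#' Raw mode sums the three raw component indices; graded mode sums their
#' 1..5 equal-interval scores (pass the grades via `grades`). Contribution
#' rates are each component over the total and sum to one.
#'
#' @param r_edi,r_hhi,r_rici component values (raw mode), >= 0.
#' @param mode `"raw"` or `"graded"`.
#' @param grades integer vector (g_edi, g_hhi, g_rici), required in graded
#'   mode.
#' @return list `aecsi`, `cr` (named c(edi, hhi, rici) summing to 1).
#' @export
aecsi <- function(r_edi, r_hhi, r_rici, mode = c("raw", "graded"),
                  grades = NULL) {
  mode <- match.arg(mode)
  comp <- if (mode == "raw") {
    c(edi = r_edi, hhi = r_hhi, rici = r_rici)
  } else {
    if (is.null(grades) || length(grades) != 3L) {
      stop("aecsi: graded mode needs grades = c(g_edi, g_hhi, g_rici)",
           call. = FALSE)
    }
    c(edi = grades[1], hhi = grades[2], rici = grades[3])
  }
  if (any(comp < 0)) stop("aecsi: components must be >= 0", call. = FALSE)
  total <- sum(comp)
  if (total == 0) stop("aecsi: all components zero; contribution rates undefined",
                       call. = FALSE)
  list(aecsi = total, cr = comp / total)
}

#' Dominant risk type from contribution rates
#'
#' The unique component with contribution rate strictly greater than 0.5
#' names the type; otherwise (including an exact 0.5) the record is
#' "Compound risks".
#'
#' @param cr_edi,cr_hhi,cr_rici contribution rates summing to 1.
#' @return one of "EDI risk", "HHI risk", "RICI risk", "Compound risks".
#' @export
dominant_risk <- function(cr_edi, cr_hhi, cr_rici) {
  cr <- c(cr_edi, cr_hhi, cr_rici)
  lab <- c("EDI risk", "HHI risk", "RICI risk")
  hit <- cr > 0.5
  if (sum(hit) == 1L) lab[hit] else "Compound risks"
}

#' Full per-country risk scoring for one year
#'
#' For every importer with positive imports in the year: the three raw
#' indices, grades fitted on that year's cross-country values (components
#' by the configured classifier, AECSI by equal intervals, mirroring the
#' published grading scheme), the composite, contribution rates and
#' dominant type. Countries whose components cannot be computed (e.g. zero
#' imports, missing GDP/CRI) are flagged in the `failures` attribute and do
#' not stop the run.
#'
#' @param flows a `trade_flows` object.
#' @param indicators data frame `iso3,year,gdp_usd,cri`.
#' @param year calendar year.
#' @param classifier `"jenks"` (natural breaks, default) or
#'   `"equal_interval"` for the component grades.
#' @param rici_mode see [rici()].
#' @param aecsi_mode `"raw"` or `"graded"` (see [aecsi()]).
#' @param k number of grades (5 in the published scheme).
#' @return data frame (one row per scored country): `country`, `year`,
#'   `r_edi`, `r_hhi`, `r_rici`, `aecsi`, `grade_edi`, `grade_hhi`,
#'   `grade_rici`, `grade_aecsi`, `cr_edi`, `cr_hhi`, `cr_rici`,
#'   `dominant`. Attributes: `breaks` (per-index break sets), `failures`
#'   (country -> message), `config`.
#' @export
risk_pipeline <- function(flows, indicators, year,
                          classifier = c("jenks", "equal_interval"),
                          rici_mode = c("partner_cri", "own_cri"),
                          aecsi_mode = c("raw", "graded"),
                          k = 5L) {
  classifier <- match.arg(classifier)
  rici_mode <- match.arg(rici_mode)
  aecsi_mode <- match.arg(aecsi_mode)

  importers <- sort(unique(flows$importer[flows$year == year &
                                            flows$value > 0]))
  failures <- character(0)
  rows <- vector("list", length(importers))
  for (i in seq_along(importers)) {
    co <- importers[i]
    res <- tryCatch({
      imp_total <- sum(flows$value[flows$year == year &
                                     flows$importer == co])
      idx <- match(paste(co, year), paste(indicators$iso3, indicators$year))
      if (is.na(idx)) stop("no indicator row for ", co, " in ", year)
      r_e <- edi(imp_total, indicators$gdp_usd[idx])
      r_h <- hhi(flows, co, year)
      r_r <- rici(flows, indicators, co, year, mode = rici_mode)
      data.frame(country = co, year = as.integer(year),
                 r_edi = r_e, r_hhi = r_h, r_rici = r_r,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[co] <- res else rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("risk_pipeline: no country could be scored in ", year, call. = FALSE)
  }

  classify <- function(values, method = classifier) {
    if (method == "jenks") jenks_breaks(values, k)
    else equal_interval_breaks(values, k)
  }
  degenerate <- character(0)
  # a degenerate cross-section (e.g. RICI identically 1 pre-epidemic) has
  # no 5-class partition; everyone lands in the lowest class, noted
  grade_col <- function(values, name, method = classifier) {
    b <- tryCatch(classify(values, method), error = function(e) e)
    if (inherits(b, "error")) {
      degenerate[name] <<- conditionMessage(b)
      list(breaks = NULL, grades = rep(1L, length(values)))
    } else {
      list(breaks = b, grades = assign_grades(values, b))
    }
  }
  g_e <- grade_col(out$r_edi, "edi")
  g_h <- grade_col(out$r_hhi, "hhi")
  g_r <- grade_col(out$r_rici, "rici")
  brk <- list(edi = g_e$breaks, hhi = g_h$breaks, rici = g_r$breaks)
  out$grade_edi <- g_e$grades
  out$grade_hhi <- g_h$grades
  out$grade_rici <- g_r$grades

  comp <- lapply(seq_len(nrow(out)), function(i) {
    if (aecsi_mode == "raw") {
      aecsi(out$r_edi[i], out$r_hhi[i], out$r_rici[i], mode = "raw")
    } else {
      aecsi(mode = "graded",
            grades = c(out$grade_edi[i], out$grade_hhi[i],
                       out$grade_rici[i]))
    }
  })
  out$aecsi <- vapply(comp, `[[`, numeric(1), "aecsi")
  crm <- t(vapply(comp, `[[`, numeric(3), "cr"))
  out$cr_edi <- crm[, 1]; out$cr_hhi <- crm[, 2]; out$cr_rici <- crm[, 3]

  g_a <- grade_col(out$aecsi, "aecsi", method = "equal_interval")
  brk$aecsi <- g_a$breaks
  out$grade_aecsi <- g_a$grades
  out$dominant <- vapply(seq_len(nrow(out)), function(i) {
    dominant_risk(out$cr_edi[i], out$cr_hhi[i], out$cr_rici[i])
  }, character(1))

  rownames(out) <- NULL
  structure(out,
            breaks = brk,
            degenerate = degenerate,
            failures = failures,
            config = list(year = as.integer(year), classifier = classifier,
                          rici_mode = rici_mode, aecsi_mode = aecsi_mode,
                          k = as.integer(k)))
}
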