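#' Break classification: Fisher-Jenks natural breaks and equal intervals
#'
#' Both classifiers return a `break_set` whose `edges` are the k+1 ascending
#' class boundaries (min, k-1 interior breaks, max). Classes are half-open
#' [low, high) with the last class closed, so a value sitting exactly on an
#' interior edge belongs to the upper class.
#'
#' @name grading
NULL

.new_break_set <- function(method, k, edges) {
  stopifnot(all(diff(edges) > 0))
  structure(list(method = method, k = as.integer(k), edges = edges),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat(sprintf("<break_set> %s, k = %d, edges: %s\n", x$method, x$k,
              paste(signif(x$edges, 6), collapse = ", ")))
  invisible(x)
}

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification: the partition of the sorted values into k
#' contiguous classes minimizing the total within-class sum of squared
#' deviations from class means, found by dynamic programming (exact, not
#' the heuristic reallocation variant).
#'
#' @param values numeric vector; needs at least k distinct values.
#' @param k number of classes (>= 2); risk grading uses k = 5.
#' @return a `break_set`; interior edge j is the smallest value of class
#'   j + 1. Attribute `wss` holds the optimal within-class sum of squares.
#' @export
jenks_breaks <- function(values, k = 5L) {
  v <- sort(as.numeric(values))
  if (any(!is.finite(v))) stop("jenks_breaks: non-finite values", call. = FALSE)
  if (k < 2) stop("jenks_breaks: k must be >= 2", call. = FALSE)
  if (length(unique(v)) < k) {
    stop("jenks_breaks: need at least k distinct values (",
         length(unique(v)), " < ", k, ")", call. = FALSE)
  }
  n <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  # ssd of v[i..j], O(1) via prefix sums
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  # dp[c, j]: min total ssd of v[1..j] split into c classes
  dp <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) dp[1L, j] <- ssd(1L, j)
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf; barg <- 0L
      for (i in c:j) {  # class c is v[i..j]
        cand <- dp[c - 1L, i - 1L] + ssd(i, j)
        if (cand < best - 1e-12) { best <- cand; barg <- i }
      }
      dp[c, j] <- best
      back[c, j] <- barg
    }
  }
  # recover class start indices
  starts <- integer(k)
  j <- n
  for (c in k:2) {
    starts[c] <- back[c, j]
    j <- starts[c] - 1L
  }
  starts[1L] <- 1L
  # a boundary inside a run of tied values would make classes ambiguous;
  # push it forward to the next distinct value (stable, value order)
  for (c in 2:k) {
    if (v[starts[c] - 1L] == v[starts[c]]) {
      nxt <- which(v > v[starts[c]])[1L]
      if (is.na(nxt)) stop("jenks_breaks: ties leave fewer than k classes",
                           call. = FALSE)
      starts[c] <- nxt
    }
  }
  # interior edge j sits midway between the last value of class j and the
  # first of class j+1, so edges stay strictly ascending even when a class
  # is a single extreme value
  mid <- (v[starts[-1L] - 1L] + v[starts[-1L]]) / 2
  edges <- c(v[1L], mid, v[n])
  bs <- .new_break_set("jenks", k, edges)
  attr(bs, "wss") <- dp[k, n]
  bs
}

#' Equal-interval breaks
#'
#' Edges at min + j * (max - min) / k for j = 0..k.
#'
#' @param values numeric vector with max > min.
#' @param k number of classes (>= 2).
#' @return a `break_set`.
#' @export
equal_interval_breaks <- function(values, k = 5L) {
  v <- as.numeric(values)
  if (k < 2) stop("equal_interval_breaks: k must be >= 2", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stop("equal_interval_breaks: degenerate range (max == min)",
                       call. = FALSE)
  edges <- lo + (0:k) * (hi - lo) / k
  edges[1L] <- lo; edges[k + 1L] <- hi  # exact endpoints
  .new_break_set("equal_interval", k, edges)
}

#' Assign class ids 1..k from a break set
#'
#' Half-open classes [low, high), last class closed; a value equal to an
#' interior edge goes to the upper class. Out-of-range values clamp to the
#' end classes with one warning per call.
#'
#' @param values numeric vector.
#' @param breaks a `break_set`.
#' @return integer vector of class ids in 1..k.
#' @export
assign_grades <- function(values, breaks) {
  stopifnot(inherits(breaks, "break_set"))
  v <- as.numeric(values)
  edges <- breaks$edges
  k <- breaks$k
  out_of_range <- v < edges[1L] | v > edges[k + 1L]
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE),
            " value(s) outside the break range; clamped to end classes",
            call. = FALSE)
  }
  # boundary -> upper class: left-closed intervals on interior edges
  cls <- findInterval(v, edges[2:k], left.open = FALSE) + 1L
  pmin(pmax(cls, 1L), k)
}

#' Total within-class sum of squared deviations for a classification
#'
#' @param values numeric vector.
#' @param breaks a `break_set`.
#' @return the within-class SS (the quantity Fisher-Jenks minimizes).
#' @export
within_class_ss <- function(values, breaks) {
  cls <- assign_grades(values, breaks)
  sum(tapply(as.numeric(values), cls,
             function(x) sum((x - mean(x))^2)))
}

#' Serialize a break set to JSON
#'
#' @param breaks a `break_set`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
breaks_to_json <- function(breaks, path = NULL) {
  js <- jsonlite::toJSON(list(method = breaks$method, k = breaks$k,
                              edges = breaks$edges),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
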