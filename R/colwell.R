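#' Build a state-by-month contingency table from a wet/dry series
#'
#' Counts, for each calendar month, how often the lake was observed wet and
#' dry across years. Months with no observation simply contribute zero
#' counts; nothing is imputed.
#'
#' @param series tibble/data.frame with columns `year`, `month` (1-12) and
#'   `state` (1/0, `"wet"`/`"dry"`, or logical).
#' @return A 2 x 12 integer matrix with rows `wet`, `dry` and columns
#'   `1`..`12`, of class `contingency_table`.
#' @export
build_contingency <- function(series) {
  if (NROW(series) == 0) abort("empty wet/dry series")
  stopifnot(all(c("year", "month", "state") %in% names(series)))
  if (any(series$month < 1 | series$month > 12)) abort("months must be in 1..12")
  if (anyDuplicated(series[c("year", "month")])) {
    abort("duplicate (year, month) records in series")
  }
  st <- series$state
  if (is.character(st)) st <- as.integer(st == "wet") else st <- as.integer(as.logical(st) | st == 1)
  wet <- tapply(st, factor(series$month, levels = 1:12), sum, default = 0L)
  tot <- tapply(st, factor(series$month, levels = 1:12), length, default = 0L)
  tab <- rbind(wet = as.integer(wet), dry = as.integer(tot - wet))
  colnames(tab) <- as.character(1:12)
  class(tab) <- c("contingency_table", class(tab))
  tab
}

#' Colwell's constancy, contingency and predictability
#'
#' Information-theoretic decomposition of a state-by-time contingency
#' table. With column (month) totals `X_j`, row (state) totals `Y_i`, grand
#' total `Z` and `s` states: `H(X) = -sum (X_j/Z) log(X_j/Z)`, `H(Y)`
#' likewise over rows, `H(XY)` over cells (with `0 log 0 := 0`). Then
#' constancy `C = 1 - H(Y)/log s`, contingency `M = (H(X)+H(Y)-H(XY))/log s`
#' and predictability `P = C + M`. All three lie in \[0, 1\] and the log
#' base cancels. The hydroperiod is the wet fraction of all observations.
#'
#' @param table a 2 x 12 matrix from [build_contingency()] (any
#'   states x times matrix works; rows are states).
#' @return One-row tibble: `constancy`, `contingency`, `predictability`,
#'   `hydroperiod` (the latter `NA` unless a row is named `wet`).
#' @export
colwell_indices <- function(table) {
  tab <- unclass(as.matrix(table))
  z <- sum(tab)
  if (z <= 0) abort("contingency table has zero total")
  s <- nrow(tab)
  hx <- -sum(.xlogx(colSums(tab) / z))
  hy <- -sum(.xlogx(rowSums(tab) / z))
  hxy <- -sum(.xlogx(tab / z))
  constancy <- 1 - hy / log(s)
  contingency <- (hx + hy - hxy) / log(s)
  hyd <- if ("wet" %in% rownames(tab)) sum(tab["wet", ]) / z else NA_real_
  tibble(
    constancy = constancy, contingency = contingency,
    predictability = constancy + contingency, hydroperiod = hyd
  )
}

#' Predictability indices straight from a wet/dry series
#'
#' Convenience wrapper: [build_contingency()] then [colwell_indices()].
#'
#' @param series a wet/dry series (see [build_contingency()]).
#' @return One-row tibble of indices.
#' @export
colwell <- function(series) colwell_indices(build_contingency(series))

#' Read/write wet-dry series TSVs
#'
#' Plain TSV with columns `year`, `month`, `state` (0/1).
#'
#' @param path file path.
#' @return `read_wetdry()` returns the series tibble; `write_wetdry()`
#'   returns `path` invisibly.
#' @export
read_wetdry <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    year = readr::col_integer(), month = readr::col_integer(),
    state = readr::col_integer()
  ))
}

#' @param series series tibble to write.
#' @rdname read_wetdry
#' @export
write_wetdry <- function(series, path) {
  readr::write_tsv(series, path)
  invisible(path)
}
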