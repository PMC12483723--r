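#' Ordinal panel container
#'
#' Wraps a wide-format matrix of ordered categorical repeated measures: one
#' row per subject, one integer column per variable-occasion, categories
#' coded `0..C-1`.  Columns are ordered variable-block major: all `T`
#' occasions of the first variable, then all occasions of the second, and
#' so on.  Rows with any missing cell are removed (listwise deletion); the
#' sample sizes before and after deletion are recorded.
#'
#' @param data matrix or data.frame, `n x (V*T)`, integer category codes
#'   (or values coercible to integers); `NA` allowed.
#' @param n_occasions occasions per variable (`T >= 2`).
#' @param var_names optional variable labels (length `V`).
#' @param n_cat optional integer vector of category counts per variable;
#'   defaults to `max(code) + 1` observed for that variable.
#' @return an object of class `ordinal_panel` with elements `data`
#'   (complete-case integer matrix), `var_names`, `T`, `C` (per variable),
#'   `n`, `n_before`.
#' @examples
#' x <- matrix(sample(0:3, 60, TRUE), nrow = 10)
#' p <- ordinal_panel(x, n_occasions = 6)
#' p$n
#' @export
ordinal_panel <- function(data, n_occasions, var_names = NULL, n_cat = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("panel data must be numeric category codes")
  if (n_occasions < 2) stop("at least two occasions are required")
  if (ncol(data) %% n_occasions != 0)
    stop("number of columns is not a multiple of the number of occasions")
  V <- ncol(data) / n_occasions
  if (is.null(var_names)) var_names <- paste0("y", seq_len(V))
  if (length(var_names) != V) stop("var_names length does not match")
  storage.mode(data) <- "integer"

  n_before <- nrow(data)
  keep <- stats::complete.cases(data)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 1) stop("no complete cases after listwise deletion")

  if (is.null(n_cat)) {
    n_cat <- vapply(seq_len(V), function(v) {
      max(data[, (v - 1) * n_occasions + seq_len(n_occasions)]) + 1L
    }, integer(1))
  }
  n_cat <- as.integer(rep_len(n_cat, V))
  if (any(n_cat < 2)) stop("each variable needs at least 2 categories")
  for (v in seq_len(V)) {
    cols <- (v - 1) * n_occasions + seq_len(n_occasions)
    vals <- data[, cols]
    if (any(vals < 0) || any(vals > n_cat[v] - 1))
      stop(sprintf("variable '%s' has codes outside 0..%d",
                   var_names[v], n_cat[v] - 1L))
  }
  colnames(data) <- unlist(lapply(seq_len(V), function(v)
    paste0(var_names[v], "_t", seq_len(n_occasions))))
  structure(list(data = data, var_names = var_names,
                 T = as.integer(n_occasions), C = n_cat,
                 n = nrow(data), n_before = n_before),
            class = "ordinal_panel")
}

#' @export
print.ordinal_panel <- function(x, ...) {
  cat(sprintf("ordinal_panel: %d subjects (%d before listwise deletion)\n",
              x$n, x$n_before))
  cat(sprintf("  %d variable(s) x %d occasions; categories: %s\n",
              length(x$var_names), x$T,
              paste(x$C, collapse = ", ")))
  invisible(x)
}

# column index for (variable, occasion)
panel_col <- function(panel, var, t) (var - 1L) * panel$T + t

# number of categories for a given column
col_ncat <- function(panel, j) panel$C[(j - 1L) %/% panel$T + 1L]

#' Read an ordinal panel from a delimited text file
#'
#' Reads a wide CSV/TSV file (header row, one row per subject) and builds
#' an [ordinal_panel()].  Non-numeric category labels can be mapped through
#' `levels`, a character vector giving the ordered labels (coded
#' `0..length(levels)-1`).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param n_occasions,var_names,n_cat passed to [ordinal_panel()].
#' @param columns optional character vector selecting/ordering the data
#'   columns (variable-block major).
#' @param levels optional ordered label-to-code mapping.
#' @return an `ordinal_panel`.
#' @export
read_panel <- function(path, n_occasions, var_names = NULL, n_cat = NULL,
                       columns = NULL, levels = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    miss <- setdiff(columns, names(df))
    if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
    df <- df[, columns, drop = FALSE]
  }
  if (!is.null(levels)) {
    df[] <- lapply(df, function(x) {
      m <- match(as.character(x), levels) - 1L
      m[is.na(x)] <- NA_integer_
      if (any(is.na(m) & !is.na(x)))
        stop("unmappable category labels in ", path)
      m
    })
  } else {
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad))
      stop("non-numeric columns without a 'levels' mapping: ",
           paste(names(df)[bad], collapse = ", "))
    nonint <- vapply(df, function(x)
      any(abs(x - round(x)) > 0, na.rm = TRUE), logical(1))
    if (any(nonint)) stop("non-integer category codes in ", path)
  }
  ordinal_panel(df, n_occasions, var_names = var_names, n_cat = n_cat)
}

#' Per-column category margins
#'
#' Category counts and proportions for every variable-occasion column.
#' Occasions where some category is unobserved are flagged `degenerate`
#' (extreme empty categories push the corresponding thresholds to
#' infinity; interior empty categories make the polychoric layer refuse).
#'
#' @param panel an [ordinal_panel()].
#' @return list of class `margin_table`, one element per column with
#'   `counts`, `props`, `n`, `degenerate`.
#' @export
margins <- function(panel) {
  stopifnot(inherits(panel, "ordinal_panel"))
  out <- lapply(seq_len(ncol(panel$data)), function(j) {
    C <- col_ncat(panel, j)
    cnt <- tabulate(panel$data[, j] + 1L, nbins = C)
    list(counts = cnt, props = cnt / panel$n, n = panel$n,
         degenerate = any(cnt == 0L))
  })
  names(out) <- colnames(panel$data)
  class(out) <- "margin_table"
  out
}

#' Bivariate contingency table for two panel columns
#'
#' @param panel an [ordinal_panel()].
#' @param i,j column indices (variable-occasion columns), `i != j`.
#' @return integer matrix of cell counts (`C_i x C_j`).
#' @export
crosstab <- function(panel, i, j) {
  stopifnot(inherits(panel, "ordinal_panel"), i != j)
  Ci <- col_ncat(panel, i); Cj <- col_ncat(panel, j)
  code <- panel$data[, i] * Cj + panel$data[, j] + 1L
  tab <- matrix(tabulate(code, nbins = Ci * Cj), Ci, Cj, byrow = TRUE)
  dimnames(tab) <- list(paste0("r", 0:(Ci - 1)), paste0("c", 0:(Cj - 1)))
  tab
}
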