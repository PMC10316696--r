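#' Variable metadata descriptor
#'
#' Describes one column of a mixed dataset: either a continuous measurement
#' or an ordinal-categorical variable with a declared, ordered set of level
#' codes. Ordinal levels are mapped to integer codes `0..L-1` in declared
#' order at load time and treated as Gaussian-approximate downstream; nominal
#' (unordered) categorical variables are not supported.
#'
#' @param name Variable name (unique within a dataset).
#' @param kind Either `"continuous"` or `"ordinal"`.
#' @param levels For ordinal variables, the ordered vector of level codes
#'   (at least two); must be empty for continuous variables.
#' @return A `kd_variable_meta` object.
#' @export
variable_meta <- function(name, kind = c("continuous", "ordinal"),
                          levels = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (kind == "ordinal" && length(levels) < 2L)
    stop("ordinal variable '", name, "' must declare at least 2 levels")
  if (kind == "continuous" && length(levels) > 0L)
    stop("continuous variable '", name, "' must not declare levels")
  if (anyDuplicated(levels))
    stop("duplicate level codes for variable '", name, "'")
  structure(list(name = name, kind = kind, levels = levels),
            class = "kd_variable_meta")
}

#' Construct a validated mixed dataset
#'
#' @param values Numeric N x M matrix; ordinal columns must hold the integer
#'   codes `0..L-1`.
#' @param meta List of [variable_meta()] objects, one per column.
#' @param sample_ids Optional character vector of row identifiers.
#' @return A `kd_dataset` object with fields `values`, `meta`, `sample_ids`.
#' @export
kd_dataset <- function(values, meta, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("a dataset needs at least 2 samples and 2 variables")
  if (length(meta) != ncol(values))
    stop("metadata describes ", length(meta), " variables but the table has ",
         ncol(values), " columns")
  nm <- vapply(meta, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("variable names must be unique")
  if (anyNA(values)) {
    bad <- nm[unique(which(is.na(values), arr.ind = TRUE)[, 2L])]
    stop("missing values are not supported (drop incomplete samples upstream); ",
         "affected variables: ", paste(bad, collapse = ", "))
  }
  for (j in seq_along(meta)) {
    m <- meta[[j]]
    if (m$kind == "ordinal") {
      codes <- seq_along(m$levels) - 1L
      if (!all(values[, j] %in% codes))
        stop("variable '", m$name, "' contains codes outside its declared ",
             length(m$levels), " levels")
    }
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match the number of rows")
  colnames(values) <- nm
  rownames(values) <- sample_ids
  structure(list(values = values, meta = meta, sample_ids = sample_ids),
            class = "kd_dataset")
}

#' @export
print.kd_dataset <- function(x, ...) {
  kinds <- variable_kinds(x)
  cat("<kd_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " variables (", sum(kinds == "continuous"), " continuous, ",
      sum(kinds == "ordinal"), " ordinal)\n", sep = "")
  invisible(x)
}

#' @export
dim.kd_dataset <- function(x) dim(x$values)

variable_names <- function(d) vapply(d$meta, function(m) m$name, character(1))

variable_kinds <- function(d) vapply(d$meta, function(m) m$kind, character(1))

#' Load a delimited table plus its variable-metadata sidecar
#'
#' The table must be delimited text with a header row; the sidecar (YAML or
#' JSON, selected by file extension) must declare every column as a list of
#' `{name, kind, levels}` records. Ordinal values are matched against the
#' declared level codes and stored as integer codes `0..L-1` preserving the
#' declared order. Any missing value is a hard error.
#'
#' @param table_path Path to a CSV/TSV file with header.
#' @param meta_path Path to the YAML/JSON metadata sidecar.
#' @param sep Field separator; guessed from the table extension by default.
#' @return A [kd_dataset()].
#' @export
load_dataset <- function(table_path, meta_path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", table_path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(table_path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_raw <- if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
    jsonlite::fromJSON(meta_path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(meta_path)
  }
  if (!is.null(meta_raw$variables)) meta_raw <- meta_raw$variables
  meta <- lapply(meta_raw, function(m)
    variable_meta(m$name, m$kind,
                  if (is.null(m$levels)) character() else as.character(m$levels)))
  nm <- vapply(meta, function(m) m$name, character(1))

  sample_ids <- NULL
  first <- names(tab)[1L]
  if (!(first %in% nm) && tolower(first) %in% c("sample", "sample_id", "id", "")) {
    sample_ids <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
  }
  missing_meta <- setdiff(names(tab), nm)
  if (length(missing_meta))
    stop("columns missing from metadata: ", paste(missing_meta, collapse = ", "))
  absent <- setdiff(nm, names(tab))
  if (length(absent))
    stop("metadata declares columns absent from the table: ",
         paste(absent, collapse = ", "))
  tab <- tab[, nm, drop = FALSE]

  values <- matrix(NA_real_, nrow(tab), length(nm))
  for (j in seq_along(meta)) {
    m <- meta[[j]]
    cell <- tab[[j]]
    if (m$kind == "continuous") {
      num <- suppressWarnings(as.numeric(cell))
      if (anyNA(num))
        stop("non-numeric or missing value in continuous column '", m$name, "'")
      values[, j] <- num
    } else {
      code <- match(as.character(cell), m$levels) - 1L
      if (anyNA(code))
        stop("unknown level code in ordinal column '", m$name, "': ",
             paste(unique(cell[is.na(code)]), collapse = ", "))
      values[, j] <- code
    }
  }
  kd_dataset(values, meta, sample_ids)
}

#' Write a dataset back to a delimited table and metadata sidecar
#'
#' Inverse of [load_dataset()]: ordinal codes are written back as their
#' declared level labels. Numeric content round-trips losslessly (values are
#' serialized at full double precision).
#'
#' @param d A [kd_dataset()].
#' @param table_path,meta_path Output paths; the metadata format follows the
#'   extension of `meta_path` (`.json` or YAML otherwise).
#' @param sep Field separator (default tab).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(d, table_path, meta_path, sep = "\t") {
  stopifnot(inherits(d, "kd_dataset"))
  out <- as.data.frame(d$values, check.names = FALSE)
  for (j in seq_along(d$meta)) {
    m <- d$meta[[j]]
    out[[j]] <- if (m$kind == "ordinal") m$levels[d$values[, j] + 1L]
                else format(d$values[, j], digits = 17, trim = TRUE,
                            scientific = FALSE)
  }
  out <- cbind(sample_id = d$sample_ids, out)
  utils::write.table(out, table_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  meta_list <- lapply(d$meta, function(m)
    list(name = m$name, kind = m$kind, levels = as.list(m$levels)))
  if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
    jsonlite::write_json(list(variables = meta_list), meta_path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(list(variables = meta_list), meta_path)
  }
  invisible(c(table_path, meta_path))
}

#' Standardize dataset columns to zero mean and unit standard deviation
#'
#' @param d A [kd_dataset()].
#' @param which `"continuous_only"` (default) standardizes continuous columns
#'   and leaves ordinal codes untouched; `"all"` standardizes every column.
#' @return A list with `dataset` (transformed copy), and `center`/`scale`
#'   vectors (per-column mean and sd; untouched columns get 0/1) usable with
#'   [unstandardize()].
#' @export
standardize <- function(d, which = c("continuous_only", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(d, "kd_dataset"))
  kinds <- variable_kinds(d)
  idx <- if (which == "all") seq_along(kinds) else which(kinds == "continuous")
  center <- rep(0, ncol(d$values))
  scale <- rep(1, ncol(d$values))
  names(center) <- names(scale) <- variable_names(d)
  vals <- d$values
  for (j in idx) {
    mu <- mean(vals[, j])
    sd_j <- stats::sd(vals[, j])
    if (!is.finite(sd_j) || sd_j <= 0)
      stop("cannot standardize constant column '", variable_names(d)[j], "'")
    vals[, j] <- (vals[, j] - mu) / sd_j
    center[j] <- mu
    scale[j] <- sd_j
  }
  out <- d
  out$values <- vals
  list(dataset = out, center = center, scale = scale)
}

#' Invert a standardization transform
#'
#' @param d A standardized [kd_dataset()].
#' @param center,scale Per-column transform parameters from [standardize()].
#' @return The dataset on its original scale.
#' @export
unstandardize <- function(d, center, scale) {
  stopifnot(inherits(d, "kd_dataset"))
  out <- d
  out$values <- sweep(sweep(d$values, 2, scale, "*"), 2, center, "+")
  out
}

#' Inverse-covariance candidate screen
#'
#' Optional preprocessing filter: a variable pair is admissible when the
#' corresponding entry of the inverse sample covariance exceeds `tol` in
#' absolute value, i.e. the pair is not conditionally independent given all
#' other variables under a Gaussian working model. When the covariance is
#' singular (e.g. N <= M) a small ridge proportional to the average variance
#' is added before inversion, or an error is raised when `ridge = 0`.
#'
#' @param d A [kd_dataset()].
#' @param tol Admissibility threshold on `|Omega_ij|` (default `1e-4`).
#' @param ridge Ridge multiplier: the diagonal is inflated by
#'   `ridge * trace/M` when plain inversion fails (default `1e-6`).
#' @return Data frame of admissible pairs with columns `var_a`, `var_b`,
#'   `omega` (the inverse-covariance entry).
#' @export
precision_screen <- function(d, tol = 1e-4, ridge = 1e-6) {
  stopifnot(inherits(d, "kd_dataset"))
  S <- stats::cov(d$values)
  omega <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(omega)) {
    if (ridge <= 0)
      stop("sample covariance is singular (N <= M?); rerun with a positive ",
           "ridge or reduce the variable count")
    S2 <- S + diag(ridge * sum(diag(S)) / ncol(S), ncol(S))
    omega <- solve(S2)
  }
  nm <- variable_names(d)
  pairs <- which(upper.tri(omega) & abs(omega) >= tol, arr.ind = TRUE)
  data.frame(var_a = nm[pairs[, 1L]], var_b = nm[pairs[, 2L]],
             omega = omega[pairs], stringsAsFactors = FALSE)
}
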