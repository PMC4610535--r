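# Readers and writers for the package's plain-text exchange formats: layout
# JSON, sample / census / estimate CSV, covariance long-form CSV, audit JSON.

fmt17 <- function(x) sprintf("%.17g", x)

#' Read and write a state layout as JSON
#'
#' Serialized as `{"study": [...], "times": [...], "aux": [...]}`.
#'
#' @param path file path
#' @param layout a [state_layout()]
#' @return `read_layout` returns a [state_layout()]
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("study", "times")) {
    if (is.null(obj[[f]])) stop("layout JSON is missing field '", f, "'")
  }
  state_layout(obj$study, obj$times,
               if (is.null(obj$aux)) character() else obj$aux)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "state_layout"))
  jsonlite::write_json(
    list(study = layout$study, times = layout$times, aux = layout$aux),
    path
  )
  invisible(path)
}

#' Read a sample table from CSV
#'
#' The header must contain `unit_id`, `panel`, optionally `stratum`, and
#' exactly the state-variable columns of the layout (any order).  Unknown or
#' missing columns and non-numeric cells are rejected with their names.
#'
#' @param path CSV file path
#' @param layout the [state_layout()]
#' @return a sample table (data frame), value columns in layout order
#' @export
read_sample <- function(path, layout) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- state_names(layout)
  reserved <- c("unit_id", "panel", "stratum")
  have <- setdiff(colnames(df), reserved)
  missing <- setdiff(nm, have)
  if (length(missing)) {
    stop("sample CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(have, nm)
  if (length(extra)) {
    stop("sample CSV has unknown column(s): ", paste(extra, collapse = ", "))
  }
  for (v in nm) {
    col <- df[[v]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("non-numeric value in sample CSV at row ", bad[1L],
             ", column '", v, "'")
      }
      df[[v]] <- num
    }
  }
  keep <- c(intersect(reserved, colnames(df)), nm)
  df[, keep, drop = FALSE]
}

#' @rdname read_sample
#' @param sample a sample table
#' @export
write_sample <- function(sample, path) {
  out <- sample
  nm <- setdiff(colnames(out), c("unit_id", "panel", "stratum"))
  for (v in nm) out[[v]] <- fmt17(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read census constants
#'
#' Accepts a two-column CSV (`name,value`) or a JSON object mapping
#' auxiliary names to values.  Every auxiliary in the layout must be
#' present; unknown names are rejected.
#'
#' @param path file path (`.json` or CSV)
#' @param layout the [state_layout()]
#' @return a `census_constants`
#' @export
read_census <- function(path, layout) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    y <- unlist(obj)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "value") %in% colnames(df))) {
      stop("census CSV needs columns 'name' and 'value'")
    }
    y <- stats::setNames(as.numeric(df$value), df$name)
  }
  census_constants(y, layout)
}

#' @rdname read_census
#' @param census a `census_constants`
#' @export
write_census <- function(census, path) {
  stopifnot(inherits(census, "census_constants"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(census$y), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(
      data.frame(name = names(census$y), value = fmt17(census$y)),
      path, row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Write and read a state estimate
#'
#' The estimate CSV has columns `variable`, `value`, `SE`; the covariance
#' matrix is serialized separately in diff-friendly long form (`i,j,value`,
#' upper triangle including the diagonal).  Values are written with 17
#' significant digits so that a write/read round trip preserves them to
#' full double precision.
#'
#' @param est a [state_estimate()]
#' @param path estimate CSV path
#' @param cov_path covariance CSV path (optional on write; required to
#'   recover `V` on read)
#' @param layout the [state_layout()]
#' @return `read_estimate` returns a [state_estimate()]
#' @export
write_estimate <- function(est, path, cov_path = NULL) {
  stopifnot(inherits(est, "state_estimate"))
  df <- data.frame(variable = names(est$x),
                   value = fmt17(est$x),
                   SE = fmt17(sqrt(pmax(diag(est$V), 0))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(cov_path)) {
    ut <- which(upper.tri(est$V, diag = TRUE), arr.ind = TRUE)
    cv <- data.frame(i = ut[, 1L], j = ut[, 2L],
                     value = fmt17(est$V[ut]))
    utils::write.csv(cv, cov_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_estimate
#' @export
read_estimate <- function(path, cov_path, layout) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- state_names(layout)
  idx <- match(nm, df$variable)
  if (anyNA(idx)) {
    stop("estimate CSV is missing variable(s): ",
         paste(nm[is.na(idx)], collapse = ", "))
  }
  x <- as.numeric(df$value)[idx]
  cv <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  k <- length(nm)
  V <- matrix(0, k, k)
  V[cbind(cv$i, cv$j)] <- as.numeric(cv$value)
  V[cbind(cv$j, cv$i)] <- as.numeric(cv$value)
  state_estimate(x, V, layout = layout, validate = FALSE)
}

#' Write the per-constraint audit trail as JSON
#'
#' One record per auxiliary constraint with its status, inflation factor,
#' and the residual between the sample estimate and the census constant in
#' standard-deviation units -- the non-sampling-error diagnostic an analyst
#' should review after every run.
#'
#' @param result a `kf_result`
#' @param path output JSON path
#' @param zeroed optional matrix of covariance index pairs zeroed by
#'   [sparsify()]
#' @param mode divergence mode used (recorded verbatim)
#' @export
write_audit <- function(result, path, zeroed = NULL, mode = NULL) {
  audit <- result$audit
  records <- lapply(seq_len(nrow(audit)), function(r) {
    list(index = audit$index[r], state_index = audit$state_index[r],
         name = audit$name[r], status = audit$status[r],
         c = audit$c[r], residual_sd = audit$residual_sd[r],
         weight_norm = audit$weight_norm[r])
  })
  obj <- list(constraints = records)
  if (!is.null(mode)) obj$divergence_mode <- mode
  if (!is.null(zeroed)) {
    obj$sparsified_pairs <- if (nrow(zeroed)) {
      lapply(seq_len(nrow(zeroed)), function(r) as.list(unname(zeroed[r, ])))
    } else {
      list()
    }
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
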