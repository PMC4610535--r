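# Top-level pipeline: design estimate -> eligibility -> sparsify ->
# standardize -> sequential Kalman update -> destandardize -> sparsify ->
# post-estimation transforms -> artifacts.

#' Run the full estimation pipeline
#'
#' Sequences the package end to end: read the layout, sample and census;
#' form the design-based SRS estimate; drop variables failing the
#' nonzero-count eligibility rule; sparsify chance correlations; centre and
#' scale to unit diagonal; apply the sequential Kalman constraints;
#' transform back; sparsify again; append any post-estimation transforms;
#' write the estimate CSV (value, SE), the covariance long-form CSV and the
#' audit JSON.  On any failure partially written outputs are removed and an
#' error is raised.
#'
#' @param config a named list, or a path to a JSON/YAML file, with fields:
#'   `layout`, `sample`, `census` (paths); `out_estimate`, `out_covariance`,
#'   `out_audit` (output paths, optional); `tol`, `divergence`,
#'   `min_nonzero`, `alpha`, `sparsify_stage` (`"both"`, `"before"`,
#'   `"after"` or `"off"`), `p_adjust`, `transforms` (list of lists with
#'   `op`, `operands` as state-variable names, `name`, optional
#'   `coefficients`).  Missing fields take the defaults documented in
#'   [kf_options()], [eligibility_filter()] and [sparsify_policy()].
#' @return (invisibly) a list with the final [state_estimate()], the
#'   `kf_result`, the reduced layout, and the paths written
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- function(field, default) {
    if (is.null(config[[field]])) default else config[[field]]
  }
  for (field in c("layout", "sample", "census")) {
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
    if (!file.exists(config[[field]])) {
      stop("config path does not exist: ", config[[field]])
    }
  }

  written <- character()
  on_fail <- function(e) {
    unlink(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    layout <- read_layout(config$layout)
    sample <- read_sample(config$sample, layout)
    census <- read_census(config$census, layout)

    # eligibility: drop rare variables, align the census to the survivors
    flt <- eligibility_filter(sample, layout,
                              min_nonzero = cfg("min_nonzero", 25))
    layout2 <- flt$layout
    sample2 <- sample[, c(intersect(c("unit_id", "panel", "stratum"),
                                    colnames(sample)),
                          state_names(layout2)), drop = FALSE]
    census2 <- census_constants(census$y[layout2$aux], layout2, N = census$N)

    est <- srs_estimate(sample2, layout2)

    stage <- cfg("sparsify_stage", "both")
    policy <- if (stage != "off") {
      sparsify_policy(alpha = cfg("alpha", 0.05), n = nrow(sample2),
                      stage = if (stage == "off") "both" else stage,
                      p_adjust = cfg("p_adjust", "none"))
    }
    zeroed <- matrix(integer(), 0, 2)
    if (stage %in% c("both", "before")) {
      sp <- sparsify(est, policy)
      est <- sp$estimate
      zeroed <- rbind(zeroed, sp$zeroed)
    }

    opts <- kf_options(tol = cfg("tol", 1e-4),
                       divergence = cfg("divergence", "as_printed"))
    result <- kf_estimate(est, census2, opts)
    final <- result$estimate

    if (stage %in% c("both", "after")) {
      sp <- sparsify(final, policy)
      final <- sp$estimate
      zeroed <- rbind(zeroed, sp$zeroed)
    }

    for (tr in cfg("transforms", list())) {
      spec <- transform_spec(op = tr$op, operands = unlist(tr$operands),
                             name = tr$name, coefficients = tr$coefficients)
      final <- append_pseudo_estimate(final, spec)
    }

    out_est <- cfg("out_estimate", NULL)
    out_cov <- cfg("out_covariance", NULL)
    out_audit <- cfg("out_audit", NULL)
    if (!is.null(out_est)) {
      written <- c(written, out_est, out_cov)
      write_estimate(final, out_est, cov_path = out_cov)
    }
    if (!is.null(out_audit)) {
      written <- c(written, out_audit)
      write_audit(result, out_audit, zeroed = zeroed, mode = opts$divergence)
    }

    skipped <- sum(result$audit$status == "skipped_low_variance")
    inflated <- sum(result$audit$status == "inflated_then_applied")
    message("kfsurvey: ", layout2$k, "/", layout$k, " variables eligible; ",
            layout2$k_a - skipped, " constraint(s) applied (", inflated,
            " inflated, ", skipped, " skipped); ", nrow(zeroed),
            " covariance pair(s) zeroed")

    invisible(list(estimate = final, result = result, layout = layout2,
                   zeroed = zeroed,
                   paths = c(estimate = out_est, covariance = out_cov,
                             audit = out_audit)))
  }, error = on_fail)
}
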