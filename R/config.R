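#' Load a design / simulation configuration file
#'
#' Reads a YAML or JSON configuration with blocks \code{design}, \code{oc},
#' \code{prior}, and \code{mcmc}, validates every field through the
#' constructors, and rejects unknown keys by name.
#'
#' Recognized keys: \code{design} accepts \code{event_rates},
#' \code{n_stage1_per_arm}, \code{n_stage2_per_arm}, \code{threshold_delta},
#' \code{surrogate_maturation_weeks}, \code{followup_weeks},
#' \code{enrollment_rate}, \code{dropout_3yr}, \code{alpha_one_sided},
#' \code{n_select}, \code{weights}, \code{arm_names}; \code{oc} accepts
#' \code{n_replicates}, \code{parameter_mode}, \code{fixed_params},
#' \code{master_seed}, \code{compute_counterfactual}; \code{prior} accepts
#' \code{shape}, \code{rate}, \code{prior_on}; \code{mcmc} accepts
#' \code{draws}, \code{burnin}, \code{seed}.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A list with elements \code{design} (\code{\link{design_config}}),
#'   \code{oc} (\code{\link{oc_config}}), \code{prior}
#'   (\code{\link{prior_spec}}), and \code{mcmc} (list: draws, burnin,
#'   seed).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0L) {
    stop("configuration error: empty config file ", path)
  }
  known_top <- c("design", "oc", "prior", "mcmc")
  .reject_unknown(raw, known_top, "top level")

  dsgn <- raw$design
  if (!is.null(dsgn)) {
    .reject_unknown(dsgn, c("event_rates", "n_stage1_per_arm",
                            "n_stage2_per_arm", "threshold_delta",
                            "surrogate_maturation_weeks", "followup_weeks",
                            "enrollment_rate", "dropout_3yr",
                            "alpha_one_sided", "n_select", "weights",
                            "arm_names"), "design")
  }
  ocb <- raw$oc
  if (!is.null(ocb)) {
    .reject_unknown(ocb, c("n_replicates", "parameter_mode", "fixed_params",
                           "master_seed", "compute_counterfactual"), "oc")
  }
  prb <- raw$prior
  if (!is.null(prb)) {
    .reject_unknown(prb, c("shape", "rate", "prior_on"), "prior")
  }
  mcb <- raw$mcmc
  if (!is.null(mcb)) {
    .reject_unknown(mcb, c("draws", "burnin", "seed"), "mcmc")
  }

  design <- do.call(design_config, .drop_null(list(
    event_rates_3yr = dsgn$event_rates,
    n_stage1_per_arm = dsgn$n_stage1_per_arm,
    n_stage2_per_arm = dsgn$n_stage2_per_arm,
    threshold_delta = dsgn$threshold_delta,
    surrogate_maturation_weeks = dsgn$surrogate_maturation_weeks,
    followup_weeks = dsgn$followup_weeks,
    enrollment_rate = dsgn$enrollment_rate,
    dropout_3yr = dsgn$dropout_3yr,
    alpha_one_sided = dsgn$alpha_one_sided,
    n_select = dsgn$n_select,
    weights = unlist(dsgn$weights),
    arm_names = unlist(dsgn$arm_names))))
  fp <- if (!is.null(ocb$fixed_params)) {
    unlist(ocb$fixed_params)
  } else NULL
  oc <- do.call(oc_config, .drop_null(list(
    n_replicates = ocb$n_replicates,
    parameter_mode = ocb$parameter_mode,
    fixed_params = fp,
    master_seed = ocb$master_seed,
    compute_counterfactual = ocb$compute_counterfactual)))
  prior <- do.call(prior_spec, .drop_null(list(
    shape = prb$shape, rate = prb$rate, prior_on = prb$prior_on)))
  mcmc <- list(draws = if (is.null(mcb$draws)) 6000L else mcb$draws,
               burnin = if (is.null(mcb$burnin)) 1000L else mcb$burnin,
               seed = if (is.null(mcb$seed)) 1L else mcb$seed)
  list(design = design, oc = oc, prior = prior, mcmc = mcmc)
}

.reject_unknown <- function(block, known, where) {
  extra <- setdiff(names(block), known)
  if (length(extra) > 0L) {
    stop("configuration error: unknown key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
  }
}

.drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' Flatten operating-characteristics results into a table
#'
#' @param results A single \code{"oc_result"} or a list of them (e.g. from
#'   \code{\link{threshold_sweep}}).
#' @return A data.frame, one row per result, with all probabilities as full
#'   doubles plus their Monte-Carlo standard errors.
#' @export
oc_table <- function(results) {
  if (inherits(results, "oc_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to tabulate")
  rows <- lapply(results, function(r) {
    sel <- as.list(r$p_select)
    names(sel) <- paste0("p_select_", names(sel))
    sel_se <- as.list(r$mc_se$p_select)
    names(sel_se) <- paste0("se_select_", names(r$p_select))
    as.data.frame(c(list(threshold_delta = r$threshold_delta,
                         p_carry_forward = r$p_carry_forward,
                         p_futility = r$p_futility,
                         overall_power = r$overall_power,
                         conditional_power = r$conditional_power,
                         false_stopping = r$false_stopping,
                         expected_n = r$expected_n,
                         mean_analysed_n = r$mean_analysed_n,
                         n_replicates = r$n_replicates,
                         se_carry_forward = r$mc_se$p_carry_forward,
                         se_overall_power = r$mc_se$overall_power,
                         se_false_stopping = r$mc_se$false_stopping),
                    sel, sel_se))
  })
  do.call(rbind, rows)
}

#' Write an operating-characteristics table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' round-trip read reproduces the doubles bitwise.
#'
#' @param results As for \code{\link{oc_table}}, or an already-flattened
#'   data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_oc_table <- function(results, path) {
  tab <- if (is.data.frame(results)) results else oc_table(results)
  fmt <- tab
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an operating-characteristics CSV
#' @param path Path written by \code{\link{write_oc_table}}.
#' @return A data.frame with numeric columns restored.
#' @export
read_oc_table <- function(path) {
  utils::read.csv(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration snapshot, the master seed, package and R
#' versions, the wall clock, and the inventory of output files, as JSON.
#'
#' @param path Output path for the manifest.
#' @param config A list (e.g. from \code{\link{load_config}}) snapshotting
#'   the run configuration.
#' @param master_seed Integer seed of the run.
#' @param outputs Character vector of files the run wrote.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(path, config, master_seed, outputs) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing) > 0L) {
    stop("manifest lists unwritten output(s): ",
         paste(missing, collapse = ", "))
  }
  manifest <- list(
    package = "surradapt",
    version = as.character(utils::packageVersion("surradapt")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    config = .unclass_deep(config),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_deep) else x
}
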