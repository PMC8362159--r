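#' Imputation accuracy: correlation of true and imputed genotypes
#'
#' Pearson correlation over the markers where the imputed genotype is
#' non-missing (missing true genotypes are also excluded). `NA` when either
#' vector is constant over those markers.
#'
#' @param true_gt,imputed_gt genotype vectors over the same panel.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
imputation_accuracy <- function(true_gt, imputed_gt) {
  if (length(true_gt) != length(imputed_gt))
    stop("true and imputed vectors differ in length")
  keep <- imputed_gt != MISSING & true_gt != MISSING
  if (sum(keep) < 2L) return(NA_real_)
  x <- as.numeric(true_gt[keep]); y <- as.numeric(imputed_gt[keep])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Imputation yield: fraction of Hd markers imputed non-missing
#'
#' @param imputed_gt imputed genotype vector.
#' @param n_hd total number of Hd markers (default: the vector length).
#' @return fraction in `[0, 1]`.
#' @export
imputation_yield <- function(imputed_gt, n_hd = length(imputed_gt)) {
  if (n_hd == 0L) stop("n_hd must be positive")
  sum(imputed_gt != MISSING) / n_hd
}

#' Scenario specifications of the simulation study
#'
#' Scenarios 1-4 use one to four crosses without grandparents; scenarios 5-8
#' repeat them with both grandparents genotyped at Hd.
#'
#' @param scenario scenario numbers (1-8).
#' @param parentA_inbred,parentA_genotyping passed to [scenario_spec()].
#' @param ... further arguments to [scenario_spec()] (panel and population
#'   sizes), shared by all scenarios.
#' @return named list of [scenario_spec()]s.
#' @export
study_scenarios <- function(scenario = 1:8, parentA_inbred = TRUE,
                            parentA_genotyping = "none", ...) {
  out <- lapply(scenario, function(s) {
    scenario_spec(parentA_inbred = parentA_inbred,
                  parentA_genotyping = parentA_genotyping,
                  n_crosses = ((s - 1L) %% 4L) + 1L,
                  include_grandparents = s > 4L,
                  ...)
  })
  names(out) <- paste0("scenario", scenario)
  out
}

#' Run replicated imputation scenarios
#'
#' For every scenario and replicate: simulate the population, impute the
#' target parent from its Hd relatives, and score accuracy (correlation of
#' true and imputed genotypes) and yield. Optionally a sample of Ld focal F2
#' is imputed twice -- once with the parent's true phased genotypes and once
#' with its imputed genotypes -- to measure how parent imputation error
#' propagates to the descendants.
#'
#' @param specs named list of [scenario_spec()]s (or a single spec).
#' @param n_replicates replicates per scenario.
#' @param seed base seed; per-replicate seeds are derived deterministically.
#' @param focal_n number of focal F2 per cross to impute and score (0 = skip).
#' @return data.frame of class `scenario_report`, one row per scenario and
#'   replicate, with columns `scenario`, `replicate`, `parent_accuracy`,
#'   `parent_yield` and (when `focal_n > 0`) `focal_accuracy_true`,
#'   `focal_accuracy_imputed`.
#' @export
run_scenarios <- function(specs, n_replicates = 20L, seed = 1L, focal_n = 0L) {
  if (inherits(specs, "scenario_spec")) specs <- list(scenario = specs)
  if (is.null(names(specs))) names(specs) <- paste0("scenario", seq_along(specs))
  rows <- list()
  for (si in seq_along(specs)) {
    for (r in seq_len(n_replicates)) {
      spec <- specs[[si]]
      spec$seed <- derive_seed(seed, si, r)
      rep_res <- run_one_replicate(spec, focal_n = focal_n)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(scenario = names(specs)[si], replicate = r,
                         stringsAsFactors = FALSE),
              as.data.frame(rep_res))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_report", "data.frame")
  out
}

# One simulate-impute-score replicate.
run_one_replicate <- function(spec, focal_n = 0L) {
  pop <- simulate_population(spec)
  fit <- impute_parent(pop$geno, pop$pedigree, pop$panel, target = "A")
  true_gt <- hap_genotype(pop$truth$A)
  out <- list(parent_accuracy = imputation_accuracy(true_gt, fit$genotype),
              parent_yield = imputation_yield(fit$genotype))
  if (focal_n > 0L) {
    acc_true <- acc_imp <- numeric(0)
    for (cr in pop$crosses) {
      ids <- cr$focal[seq_len(min(focal_n, length(cr$focal)))]
      mate <- pop$truth[[cr$mate]]
      for (id in ids) {
        y <- unclass(pop$geno)[id, ]
        truth <- hap_genotype(pop$truth[[id]])
        rt <- impute_focal_to_hd(y, pop$truth$A, mate, pop$panel)
        ri <- impute_focal_to_hd(y, fit, mate, pop$panel)
        acc_true <- c(acc_true, imputation_accuracy(truth, rt$genotype))
        acc_imp <- c(acc_imp, imputation_accuracy(truth, ri$genotype))
      }
    }
    out$focal_accuracy_true <- mean(acc_true, na.rm = TRUE)
    out$focal_accuracy_imputed <- mean(acc_imp, na.rm = TRUE)
  }
  out
}

# Deterministic per-replicate seed below 2^31.
derive_seed <- function(seed, scenario_idx, replicate) {
  (((seed %% 100000L) * 20011L + scenario_idx * 1009L + replicate * 7L) %%
     2147483629L) + 1L
}

#' @export
print.scenario_report <- function(x, digits = 4, ...) {
  cat("scenario report (mean +/- SD over replicates)\n")
  num <- setdiff(names(x), c("scenario", "replicate"))
  for (s in unique(x$scenario)) {
    sub <- x[x$scenario == s, num, drop = FALSE]
    cat(sprintf("  %s (n=%d):", s, nrow(sub)))
    for (v in num)
      cat(sprintf(" %s %.*f +/- %.*f", v, digits, mean(sub[[v]], na.rm = TRUE),
                  digits, stats::sd(sub[[v]], na.rm = TRUE)))
    cat("\n")
  }
  invisible(x)
}

#' Aggregate a scenario report
#'
#' @param object a [run_scenarios()] result.
#' @param ... unused.
#' @return data.frame with per-scenario mean and SD of every score.
#' @export
summary.scenario_report <- function(object, ...) {
  num <- setdiff(names(object), c("scenario", "replicate"))
  out <- do.call(rbind, lapply(unique(object$scenario), function(s) {
    sub <- object[object$scenario == s, num, drop = FALSE]
    row <- data.frame(scenario = s, n = nrow(sub))
    for (v in num) {
      row[[paste0(v, "_mean")]] <- mean(sub[[v]], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- stats::sd(sub[[v]], na.rm = TRUE)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
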