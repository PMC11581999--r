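#' Validate a twin roster against its structural invariants
#'
#' Row- and pair-level checks: at most two individuals per pair; co-twins
#' share zygosity, sex and birth year (same-sex pairs only); age equals
#' assessment year minus birth year; a reported quantity requires a
#' regular-smoking `yes` at that or an earlier assessment; zygosity and
#' quantity categories take legal values.
#'
#' @param roster A roster data frame or a path to a roster CSV.
#' @return Data frame of violations (`rule`, `id`, `message`); zero rows
#'   for a clean roster.
#' @export
validate_roster <- function(roster) {
  if (is.character(roster)) roster <- read_roster(roster)
  v <- list()
  bad <- function(rule, id, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, id = as.character(id),
                                       message = message,
                                       stringsAsFactors = FALSE)
  sz <- tapply(roster$individual_id, roster$pair_id,
               function(x) length(unique(x)))
  for (p in names(sz)[sz > 2])
    bad("pair_size", p, sprintf("pair has %d members (max 2)", sz[[p]]))
  firsts <- roster[!duplicated(roster$individual_id), ]
  for (p in unique(firsts$pair_id)) {
    tw <- firsts[firsts$pair_id == p, ]
    if (length(unique(tw$zygosity)) > 1)
      bad("shared_zygosity", p, "co-twins differ in zygosity")
    if (length(unique(tw$sex)) > 1)
      bad("same_sex_pairs", p, "co-twins differ in sex (same-sex design)")
    if (length(unique(tw$birth_year)) > 1)
      bad("shared_birth_year", p, "co-twins differ in birth year")
  }
  off <- which(roster$age != roster$assess_year - roster$birth_year)
  for (i in off)
    bad("age_consistency", roster$individual_id[i],
        "age is not assessment year minus birth year")
  if (!all(roster$zygosity %in% c("MZ", "DZ")))
    bad("zygosity_values", "-", "zygosity outside {MZ, DZ}")
  qc <- roster$quantity_category
  for (i in which(!is.na(qc) & !(qc %in% 1:8)))
    bad("quantity_range", roster$individual_id[i],
        "quantity category outside 1..8")
  ord <- order(roster$individual_id, roster$assess_year)
  r <- roster[ord, ]
  reg_ever <- ave(r$regular_item == "yes" & !is.na(r$regular_item),
                  r$individual_id, FUN = cummax)
  viol <- which(!is.na(r$quantity_category) & reg_ever == 0)
  for (i in viol)
    bad("quantity_requires_regular", r$individual_id[i],
        "quantity reported without regular smoking at that or an earlier assessment")
  if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(), id = character(),
                  message = character(), stringsAsFactors = FALSE)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 1000L) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' @param seed Root seed; every stage derives its own named substream from
#'   it, so adding a stage never perturbs earlier stages' draws.
#' @param results_dir Output directory (created if missing parent exists).
#' @param roster_csv Optional path to an external roster; when `NULL` the
#'   synthetic cohort is simulated.
#' @param n_pairs_per_zygosity Simulated pairs per zygosity per supergroup.
#' @param fit_ccc,fit_lmm,comparisons Stage switches.
#' @param lmm_n_pairs Pairs for the longitudinal stage.
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, results_dir = "results",
                            roster_csv = NULL,
                            n_pairs_per_zygosity = c(MZ = 500, DZ = 1000),
                            fit_ccc = TRUE, fit_lmm = TRUE,
                            comparisons = FALSE, lmm_n_pairs = 1000) {
  list(seed = seed, results_dir = results_dir, roster_csv = roster_csv,
       n_pairs_per_zygosity = n_pairs_per_zygosity, fit_ccc = fit_ccc,
       fit_lmm = fit_lmm, comparisons = comparisons,
       lmm_n_pairs = lmm_n_pairs)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the simulate - prepare - describe - fit - compare pipeline
#'
#' Executes the stages enabled in the config, writes every artifact under
#' `results_dir`, and returns (and writes) a manifest listing each stage's
#' outputs, status and seed.  Stage failures are recorded in the manifest;
#' stages not depending on the failed one still run.  Reruns with the same
#' config and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()] list, or a path to a JSON file with
#'   the same fields.
#' @return The manifest data frame, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config <- modifyList(pipeline_config(), config)
  dir <- config$results_dir
  if (!dir.exists(dirname(dir)))
    stop("results directory parent does not exist: ", dirname(dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file, status, msg = "")
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage,
      file = if (nzchar(file)) basename(file) else file,  # dir-relative
      status = status, seed = stage_seed(config$seed, stage),
      message = msg, stringsAsFactors = FALSE)
  stage <- function(name, deps_ok, code) {
    if (!deps_ok) {
      note(name, "", "skipped", "upstream failure")
      return(NULL)
    }
    tryCatch(code, error = function(e) {
      note(name, "", "failed", conditionMessage(e))
      NULL
    })
  }

  roster <- stage("simulate", TRUE, {
    if (!is.null(config$roster_csv)) {
      r <- read_roster(config$roster_csv)
      note("simulate", config$roster_csv, "ok", "external roster")
      r
    } else {
      sd <- stage_seed(config$seed, "simulate")
      r <- rbind(
        simulate_twin_cohort(cohort_sim_spec("earlier",
          n_pairs_per_zygosity = config$n_pairs_per_zygosity), seed = sd),
        simulate_twin_cohort(cohort_sim_spec("later",
          n_pairs_per_zygosity = config$n_pairs_per_zygosity),
          seed = sd + 1))
      r$pair_id <- paste0(rep(c("E", "L"), each = nrow(r) / 2), r$pair_id)
      r$individual_id <- paste0(rep(c("E", "L"), each = nrow(r) / 2),
                                r$individual_id)
      f <- file.path(dir, "roster.csv")
      write_roster(r, f)
      note("simulate", f, "ok")
      r
    }
  })

  ok_roster <- !is.null(roster)
  viol <- stage("validate", ok_roster, {
    vv <- validate_roster(roster)
    f <- write_tsv(vv, file.path(dir, "roster_violations.tsv"))
    note("validate", f, if (nrow(vv)) "violations" else "ok",
         sprintf("%d violation(s)", nrow(vv)))
    vv
  })

  pairs_df <- stage("prepare", ok_roster, {
    p <- pair_observations_from_roster(roster)
    note("prepare", "", "ok", sprintf("%d pairs", nrow(p)))
    p
  })

  stage("describe", ok_roster, {
    f1 <- write_tsv(prevalence_table(roster),
                    file.path(dir, "prevalence.tsv"))
    note("describe", f1, "ok")
    if (!is.null(pairs_df)) {
      f2 <- write_tsv(twin_concordance_and_correlation(pairs_df),
                      file.path(dir, "concordance.tsv"))
      note("describe", f2, "ok")
    }
  })

  fit <- NULL
  if (isTRUE(config$fit_ccc)) fit <- stage("fit-ccc", !is.null(pairs_df), {
    spec <- ccc_model_spec(sort(unique(pairs_df$group)), "components")
    ft <- fit_multigroup(pairs_df, spec,
                         control = list(seed = stage_seed(config$seed,
                                                          "fit-ccc"),
                                        n_starts = 3))
    out <- list(minus2LL = ft$minus2LL, n_free = ft$n_free,
                converged = ft$converged, seed = ft$seed,
                n_starts = ft$n_starts, convergence_code = ft$convergence,
                estimates = lapply(ft$estimates, function(p)
                  c(unclass(p), standardize_components(p))))
    f <- file.path(dir, "ccc_fit.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    note("fit-ccc", f, "ok")
    ft
  })

  if (isTRUE(config$comparisons)) stage("compare", !is.null(pairs_df), {
    cs <- run_comparison_suite(pairs_df,
                               control = list(seed = stage_seed(config$seed,
                                                                "compare")))
    f <- write_tsv(cs, file.path(dir, "comparisons.tsv"))
    note("compare", f, "ok")
  })

  if (isTRUE(config$fit_lmm)) stage("fit-lmm", TRUE, {
    d <- simulate_longitudinal_quantity(config$lmm_n_pairs,
                                        seed = stage_seed(config$seed,
                                                          "fit-lmm"))
    ft <- fit_lmm(d)
    est <- unlist(ft$params[traj_beta_names])
    tab <- data.frame(term = traj_beta_names, estimate = est,
                      se = ft$se, t = ft$tstat)
    tab <- rbind(tab, data.frame(
      term = c("var_pair", "var_individual", "var_residual",
               "marginal_R2"),
      estimate = c(ft$params$var_pair, ft$params$var_individual,
                   ft$params$var_residual, ft$r2_marginal),
      se = NA, t = NA))
    f <- write_tsv(tab, file.path(dir, "trajectory.tsv"))
    note("fit-lmm", f, "ok")
  })

  man <- do.call(rbind, manifest)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(man)
}
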