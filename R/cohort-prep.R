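cohort_breaks <- c(1880, 1901, 1911, 1921, 1931, 1941, 1951, 1958)
cohort_labels <- c("1880-1900", "1901-1910", "1911-1920", "1921-1930",
                   "1931-1940", "1941-1950", "1951-1957")

cohort_index_of <- function(birth_year) {
  findInterval(birth_year, cohort_breaks, rightmost.closed = FALSE)
}

#' Derive lifetime smoking variables from a roster
#'
#' Collapses the per-assessment ever-smoking and regular-smoking items into
#' lifetime variables: a `yes` at any assessment makes the lifetime
#' variable `yes` regardless of later quitting; all-observed-`no` responses
#' give `no`; with no observed responses the lifetime variable is missing.
#' A regular-smoking `yes` implies lifetime ever smoking (regular smokers
#' are a subset of ever smokers).
#'
#' @param roster A twin roster data frame (see [simulate_twin_cohort()]).
#' @return Data frame with columns `individual_id`, `lifetime_ever`,
#'   `lifetime_regular` (`"yes"`, `"no"` or `NA`).
#' @export
derive_lifetime_status <- function(roster) {
  collapse <- function(x) {
    if (any(x == "yes", na.rm = TRUE)) "yes"
    else if (any(x == "no", na.rm = TRUE)) "no"
    else NA_character_
  }
  ids <- unique(roster$individual_id)
  ev <- tapply(roster$ever_item, roster$individual_id, collapse)
  rg <- tapply(roster$regular_item, roster$individual_id, collapse)
  ev <- ev[ids]
  rg <- rg[ids]
  # regular 'yes' dominates: a regular smoker is an ever smoker
  ev[!is.na(rg) & rg == "yes"] <- "yes"
  data.frame(individual_id = ids, lifetime_ever = unname(ev),
             lifetime_regular = unname(rg), stringsAsFactors = FALSE)
}

#' Assign birth-cohort band, index and analysis supergroup
#'
#' Birth cohorts are 10-year bands 1901-1910 through 1951-1957, with all
#' births before 1901 grouped as 1880-1900 (index 1).  The two analysis
#' supergroups tie birth years to a defining assessment: `earlier` for
#' births 1901-1920 with a 1975 assessment, `later` for births 1945-1957
#' with a 2011 assessment; membership requires a response at the defining
#' wave, not mere birth-year eligibility.
#'
#' @param birth_year Integer vector of birth years in `[1880, 1957]`.
#' @param assessments Integer vector of assessment years with a response
#'   (applied to every birth year), or a list of such vectors, one per
#'   birth year.
#' @return Data frame with `cohort_band`, `cohort_index` (1..7) and
#'   `supergroup` (`"earlier"`, `"later"` or `"none"`).
#' @examples
#' assign_cohort(1895, 1975)               # band 1880-1900, index 1
#' assign_cohort(1915, c(1975, 1981))      # supergroup "earlier"
#' @export
assign_cohort <- function(birth_year, assessments = integer()) {
  if (any(birth_year < 1880 | birth_year > 1957))
    stop("birth_year outside [1880, 1957]: the cohort is born before 1958")
  if (!is.list(assessments))
    assessments <- rep(list(assessments), length(birth_year))
  idx <- cohort_index_of(birth_year)
  has75 <- vapply(assessments, function(a) 1975 %in% a, logical(1))
  has11 <- vapply(assessments, function(a) 2011 %in% a, logical(1))
  sg <- ifelse(birth_year >= 1901 & birth_year <= 1920 & has75, "earlier",
        ifelse(birth_year >= 1945 & birth_year <= 1957 & has11, "later",
               "none"))
  data.frame(cohort_band = cohort_labels[idx], cohort_index = idx,
             supergroup = sg, stringsAsFactors = FALSE)
}

assign_cohort_roster <- function(roster) {
  responded <- !(is.na(roster$ever_item) & is.na(roster$regular_item))
  byid <- split(roster$assess_year[responded],
                roster$individual_id[responded])
  ids <- unique(roster$individual_id)
  first <- roster[!duplicated(roster$individual_id), ]
  first <- first[match(ids, first$individual_id), ]
  asmt <- lapply(ids, function(i) byid[[i]] %||% integer())
  cbind(data.frame(individual_id = ids, sex = first$sex,
                   birth_year = first$birth_year,
                   stringsAsFactors = FALSE),
        assign_cohort(first$birth_year, asmt))
}

#' Lifetime smoking prevalence by sex and birth cohort
#'
#' Percentages of never smokers, ever-only smokers (ever but never regular)
#' and lifetime regular smokers per sex-by-cohort-band cell.  Individuals
#' whose classification cannot be determined (missing lifetime ever status,
#' or ever smokers with missing regular status) are excluded from the
#' denominator; empty cells are absent from the output rather than reported
#' as zeros.
#'
#' @param roster A twin roster data frame.
#' @return Data frame with `sex`, `cohort_band`, `n` and `pct_never`,
#'   `pct_ever_only`, `pct_regular` (each cell's percentages sum to 100).
#' @export
prevalence_table <- function(roster) {
  if (!nrow(roster)) stop("empty roster")
  st <- derive_lifetime_status(roster)
  ca <- assign_cohort_roster(roster)
  d <- merge(st, ca, by = "individual_id")
  cls <- ifelse(is.na(d$lifetime_ever), NA,
         ifelse(d$lifetime_ever == "no", "never",
         ifelse(is.na(d$lifetime_regular), NA,
         ifelse(d$lifetime_regular == "yes", "regular", "ever_only"))))
  d <- d[!is.na(cls), ]
  cls <- cls[!is.na(cls)]
  out <- list()
  for (sx in sort(unique(d$sex))) {
    for (cb in cohort_labels) {
      sel <- d$sex == sx & d$cohort_band == cb
      n <- sum(sel)
      if (!n) next
      out[[length(out) + 1L]] <- data.frame(
        sex = sx, cohort_band = cb, n = n,
        pct_never = 100 * sum(cls[sel] == "never") / n,
        pct_ever_only = 100 * sum(cls[sel] == "ever_only") / n,
        pct_regular = 100 * sum(cls[sel] == "regular") / n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Two-step estimator: the thresholds of the latent bivariate normal are
#' fixed at the normal quantiles of the margins, and the correlation is
#' estimated by maximizing the multinomial likelihood of the four cells
#' over the bivariate-normal orthant probabilities.  Perfectly concordant
#' tables return +/-1 exactly; a table with an empty margin has no defined
#' correlation and returns `NA`.
#'
#' @param tab A 2x2 matrix of counts, rows = twin 1 (no, yes), columns =
#'   twin 2 (no, yes).
#' @return Estimated correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
tetrachoric <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  p1 <- (tab[2, 1] + tab[2, 2]) / n
  p2 <- (tab[1, 2] + tab[2, 2]) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)  # empty margin
  if (tab[1, 2] == 0 && tab[2, 1] == 0) return(1)
  if (tab[1, 1] == 0 && tab[2, 2] == 0) return(-1)
  t1 <- qnorm(1 - p1)
  t2 <- qnorm(1 - p2)
  nll <- function(rho) {
    pnn <- pbvn(t1, t2, rho)
    pn1 <- pnorm(t1)
    pn2 <- pnorm(t2)
    p <- c(pnn, pn2 - pnn, pn1 - pnn, 1 - pn1 - pn2 + pnn)
    p <- pmax(p, 1e-12)
    -sum(c(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]) * log(p))
  }
  optimize(nll, c(-0.9999, 0.9999))$minimum
}

#' Twin concordances and correlations by zygosity and group
#'
#' Per zygosity-by-group cell: the number of pairs with both initiation
#' statuses observed, the pairwise initiation concordance (share of
#' concordant-affected pairs among pairs with at least one initiator), the
#' tetrachoric correlation of initiation, and the product-moment
#' correlation of quantity over pairs where both twins have an observed
#' quantity (non-smoking twins are treated as missing, so the quantity
#' correlation uses concordant-initiated complete pairs only).
#'
#' @param pairs A [pair_observations()] data frame.
#' @return Data frame with one row per zygosity-by-group cell.
#' @export
twin_concordance_and_correlation <- function(pairs) {
  pairs <- pair_observations(as.data.frame(pairs))
  out <- list()
  for (g in sort(unique(pairs$group))) {
    for (z in c("MZ", "DZ")) {
      d <- pairs[pairs$group == g & pairs$zygosity == z, , drop = FALSE]
      d <- d[!is.na(d$init1) & !is.na(d$init2), , drop = FALSE]
      if (!nrow(d)) next
      y1 <- d$init1 == "yes"
      y2 <- d$init2 == "yes"
      tab <- matrix(c(sum(!y1 & !y2), sum(!y1 & y2),
                      sum(y1 & !y2), sum(y1 & y2)), 2, 2, byrow = TRUE)
      any_yes <- sum(y1 | y2)
      conc <- if (any_yes) sum(y1 & y2) / any_yes else NA_real_
      qq <- !is.na(d$q1) & !is.na(d$q2)
      qr <- if (sum(qq) >= 3) cor(d$q1[qq], d$q2[qq]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        group = g, zygosity = z, n_pairs = nrow(d),
        concordance = conc, tetrachoric = tetrachoric(tab),
        quantity_r = qr, n_quantity_pairs = sum(qq),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

roster_columns <- c("individual_id", "pair_id", "zygosity", "sex",
                    "birth_year", "education", "assess_year", "age",
                    "ever_item", "regular_item", "quantity_category")

#' Write / read a twin roster as CSV
#'
#' The roster CSV has the fixed header `individual_id,pair_id,zygosity,
#' sex,birth_year,education,assess_year,age,ever_item,regular_item,
#' quantity_category`, one row per individual per assessment, missing
#' values encoded as empty fields.
#'
#' @param roster Roster data frame.
#' @param path File path.
#' @return `read_roster` returns the roster data frame; `write_roster`
#'   returns `path` invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster[, roster_columns], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  bad <- setdiff(roster_columns, names(d))
  extra <- setdiff(names(d), roster_columns)
  if (length(bad) || length(extra))
    stop("malformed roster header; missing column(s): ",
         paste(bad, collapse = ", "),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")))
  d[, roster_columns]
}

#' Build analysis-ready pair observations from a roster
#'
#' Joins lifetime statuses and cohort assignments, keeps individuals
#' belonging to an analysis supergroup (a response at the defining wave is
#' required), and assembles one record per twin pair: group label (sex by
#' supergroup), per-twin age at the defining assessment, initiation =
#' lifetime regular smoking, and the quantity category reported at the
#' defining assessment (missing for non-initiators).  Pairs with a single
#' supergroup member are retained as singleton observations.
#'
#' @param roster A twin roster data frame.
#' @return A [pair_observations()] data frame.
#' @export
pair_observations_from_roster <- function(roster) {
  st <- derive_lifetime_status(roster)
  ca <- assign_cohort_roster(roster)
  d <- merge(merge(st, ca, by = "individual_id"),
             roster[, c("individual_id", "pair_id", "zygosity")][
               !duplicated(roster$individual_id), ],
             by = "individual_id")
  d <- d[d$supergroup != "none", , drop = FALSE]
  if (!nrow(d)) stop("no supergroup members in roster")
  defyear <- ifelse(d$supergroup == "earlier", 1975, 2011)
  key <- paste(d$individual_id, defyear)
  rkey <- paste(roster$individual_id, roster$assess_year)
  ridx <- match(key, rkey)
  d$age <- roster$age[ridx]
  qc <- roster$quantity_category[ridx]
  d$quantity <- ifelse(!is.na(d$lifetime_regular) &
                         d$lifetime_regular == "yes", qc, NA_real_)
  d$group <- paste0(d$supergroup, "-", d$sex)
  out <- list()
  for (pid in unique(d$pair_id)) {
    tw <- d[d$pair_id == pid, , drop = FALSE]
    t1 <- tw[1, ]
    t2 <- if (nrow(tw) > 1) tw[2, ] else NULL
    out[[length(out) + 1L]] <- data.frame(
      pair_id = pid, zygosity = t1$zygosity, group = t1$group,
      age1 = t1$age, age2 = if (is.null(t2)) NA_real_ else t2$age,
      init1 = t1$lifetime_regular,
      init2 = if (is.null(t2)) NA_character_ else t2$lifetime_regular,
      q1 = t1$quantity,
      q2 = if (is.null(t2)) NA_real_ else t2$quantity,
      stringsAsFactors = FALSE)
  }
  pair_observations(do.call(rbind, out))
}
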