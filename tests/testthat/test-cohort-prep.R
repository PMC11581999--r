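mini_roster <- function(items) {
  # items: list of (id, pair, year, ever, regular, quantity)
  do.call(rbind, lapply(items, function(x)
    data.frame(individual_id = x[[1]], pair_id = x[[2]], zygosity = "MZ",
               sex = "male", birth_year = 1915,
               education = 10, assess_year = x[[3]],
               age = x[[3]] - 1915,
               ever_item = x[[4]], regular_item = x[[5]],
               quantity_category = x[[6]], stringsAsFactors = FALSE)))
}

test_that("lifetime smoking variables collapse across waves", {
  r <- mini_roster(list(
    list("a", "p1", 1975, "yes", "no", NA),     # ever then later regular
    list("a", "p1", 1981, "no", "yes", 5L),
    list("b", "p2", 1975, "no", "no", NA),      # consistently negative
    list("b", "p2", 1981, "no", "no", NA),
    list("c", "p3", 1975, NA, NA, NA),          # nothing observed
    list("c", "p3", 1981, NA, NA, NA),
    list("d", "p4", 1975, NA, "yes", 4L)))      # regular implies ever
  st <- derive_lifetime_status(r)
  st <- st[match(c("a", "b", "c", "d"), st$individual_id), ]
  expect_equal(st$lifetime_ever, c("yes", "no", NA, "yes"))
  expect_equal(st$lifetime_regular, c("yes", "no", NA, "yes"))
})

test_that("a quit regular smoker remains a lifetime regular smoker", {
  r <- mini_roster(list(list("a", "p1", 1975, "yes", "yes", 6L),
                        list("a", "p1", 1990, "yes", "no", NA)))
  st <- derive_lifetime_status(r)
  expect_equal(st$lifetime_regular, "yes")
})

test_that("adding a yes response never downgrades a lifetime status", {
  set.seed(31)
  lv <- c("yes", "no", NA)
  rank <- function(x) ifelse(is.na(x), 0L, ifelse(x == "no", 1L, 2L))
  for (i in 1:25) {
    base <- mini_roster(lapply(1:3, function(w)
      list("a", "p1", c(1975, 1981, 1990)[w], sample(lv, 1),
           sample(lv, 1), NA)))
    st0 <- derive_lifetime_status(base)
    extra <- mini_roster(list(list("a", "p1", 2011, "yes",
                                   sample(lv, 1), NA)))
    st1 <- derive_lifetime_status(rbind(base, extra))
    expect_gte(rank(st1$lifetime_ever), rank(st0$lifetime_ever))
    expect_gte(rank(st1$lifetime_regular), rank(st0$lifetime_regular))
  }
})

test_that("cohort bands partition 1880-1957 and supergroups follow the defining waves", {
  a <- assign_cohort(1895, 1975)
  expect_equal(a$cohort_band, "1880-1900")
  expect_equal(a$cohort_index, 1)
  expect_equal(assign_cohort(1915, c(1975, 1981))$supergroup, "earlier")
  expect_equal(assign_cohort(1915, 1981)$supergroup, "none")  # no 1975 wave
  expect_equal(assign_cohort(1950, 2011)$supergroup, "later")
  expect_equal(assign_cohort(1950, 1975)$supergroup, "none")
  expect_error(assign_cohort(1958, 2011), "1957")
  expect_error(assign_cohort(1879, 1975), "1957")
  # total, disjoint and exhaustive over the whole domain
  all_years <- assign_cohort(1880:1957)
  expect_equal(all_years$cohort_index,
               findInterval(1880:1957,
                            c(1880, 1901, 1911, 1921, 1931, 1941, 1951)))
  expect_true(all(table(all_years$cohort_band) ==
                    c(21, 10, 10, 10, 10, 10, 7)))
})

test_that("prevalence cells are exhaustive percentages over non-missing individuals", {
  r <- mini_roster(list(
    list("a", "p1", 1975, "yes", "yes", 5L),
    list("b", "p2", 1975, "yes", "yes", 6L),
    list("c", "p3", 1975, "yes", "no", NA),
    list("d", "p4", 1975, "no", "no", NA),
    list("e", "p5", 1975, NA, NA, NA)))  # excluded from the denominator
  tab <- prevalence_table(r)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n, 4)
  expect_equal(c(tab$pct_never, tab$pct_ever_only, tab$pct_regular),
               c(25, 25, 50))
  # all-never cell
  r2 <- mini_roster(list(list("a", "p1", 1975, "no", "no", NA),
                         list("b", "p2", 1975, "no", "no", NA)))
  t2 <- prevalence_table(r2)
  expect_equal(c(t2$pct_never, t2$pct_ever_only, t2$pct_regular),
               c(100, 0, 0))
})

test_that("prevalence percentages always sum to 100 and sex gaps follow the thresholds", {
  spec <- cohort_sim_spec("earlier",
                          n_pairs_per_zygosity = c(MZ = 800, DZ = 1600),
                          group_params = list(
                            "earlier-male" = ref_params(tau0 = 0.1),
                            "earlier-female" = ref_params(tau0 = 0.9)))
  r <- simulate_twin_cohort(spec, seed = 14)
  tab <- prevalence_table(r)
  expect_true(all(abs(tab$pct_never + tab$pct_ever_only + tab$pct_regular -
                        100) < 1e-9))
  # a lower male threshold means more male regular smokers in every band
  for (band in unique(tab$cohort_band)) {
    m <- tab[tab$sex == "male" & tab$cohort_band == band, ]
    f <- tab[tab$sex == "female" & tab$cohort_band == band, ]
    if (nrow(m) && nrow(f) && m$n > 30 && f$n > 30)
      expect_gt(m$pct_regular, f$pct_regular)
  }
})

test_that("tetrachoric correlation matches a grid-search oracle to three decimals", {
  tab <- matrix(c(40, 10, 10, 40), 2, 2)
  est <- tetrachoric(tab)
  # brute-force grid over the correlation of the orthant likelihood
  t1 <- qnorm(1 - 50 / 100)
  t2 <- qnorm(1 - 50 / 100)
  grid <- seq(-0.999, 0.999, by = 1e-4)
  ll <- vapply(grid, function(rho) {
    pnn <- phi2_quad(t1, t2, rho)
    p <- c(pnn, pnorm(t2) - pnn, pnorm(t1) - pnn,
           1 - pnorm(t1) - pnorm(t2) + pnn)
    sum(c(40, 10, 10, 40) * log(pmax(p, 1e-12)))
  }, 0)
  expect_equal(est, grid[which.max(ll)], tolerance = 1e-3)
  # boundary tables
  expect_equal(tetrachoric(matrix(c(30, 0, 0, 20), 2, 2)), 1)
  expect_equal(tetrachoric(matrix(c(0, 15, 25, 0), 2, 2)), -1)
  # an empty margin leaves the correlation undefined
  expect_true(is.na(tetrachoric(matrix(c(30, 20, 0, 0), 2, 2))))
})

test_that("twin similarity summaries respect the generating genetic structure", {
  pairs <- simulate_ccc_study(1500, seed = 16)
  cc <- twin_concordance_and_correlation(pairs)
  expect_true(all(cc$concordance >= 0 & cc$concordance <= 1))
  for (g in unique(cc$group)) {
    mz <- cc[cc$group == g & cc$zygosity == "MZ", ]
    dz <- cc[cc$group == g & cc$zygosity == "DZ", ]
    # A_init > 0 makes MZ twins more alike than DZ twins
    expect_gt(mz$tetrachoric, dz$tetrachoric)
    expect_gt(mz$quantity_r, dz$quantity_r)
  }
})

test_that("roster CSV round-trips and rejects malformed headers", {
  spec <- cohort_sim_spec("earlier", n_pairs_per_zygosity = c(MZ = 30,
                                                              DZ = 60))
  r <- simulate_twin_cohort(spec, seed = 17)
  f <- tempfile(fileext = ".csv")
  write_roster(r, f)
  r2 <- read_roster(f)
  expect_equal(r2$individual_id, r$individual_id)
  expect_equal(r2$quantity_category, r$quantity_category)
  expect_equal(r2$ever_item, r$ever_item)
  bad <- read.csv(f, stringsAsFactors = FALSE)
  names(bad)[3] <- "zygo"
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_roster(f2), "zygosity")
  expect_error(read_roster(tempfile()), "not found")
})

test_that("analysis pairs built from a roster carry supergroup, age and quantity", {
  spec <- cohort_sim_spec("earlier", n_pairs_per_zygosity = c(MZ = 150,
                                                              DZ = 300))
  r <- simulate_twin_cohort(spec, seed = 18)
  pp <- pair_observations_from_roster(r)
  expect_s3_class(pp, "pair_observations")
  expect_true(all(pp$group %in% c("earlier-male", "earlier-female")))
  expect_true(all(is.na(pp$q1) | pp$init1 == "yes"))
  expect_true(all(pp$age1 >= 55 & pp$age1 <= 75, na.rm = TRUE))
})
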