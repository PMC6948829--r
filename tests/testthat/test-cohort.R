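test_that("default registry enumerates the full battery", {
  reg <- default_registry()
  expect_equal(nrow(reg), 25)
  expect_equal(sum(reg$is_pain_outcome), 4)
  expect_false(anyDuplicated(reg$measure_id) > 0)
  expect_true(all(reg$native_min < reg$native_max))
  expect_equal(reg$community[reg$measure_id == "TUG"], "Physical Performance")
  expect_equal(reg$community[reg$measure_id == "HADS-A"], "Affect")
  expect_setequal(unique(reg$community[!reg$is_pain_outcome]),
                  c("Affect", "Pain Catastrophizing", "Pain Quality",
                    "Health", "Physical Performance"))
  expect_setequal(reg$measure_id[reg$is_pain_outcome],
                  c("NRS", "BPI-PS", "KOOS-P", "SF36-BP"))
})

test_that("registry validation rejects malformed entries", {
  reg <- as.data.frame(default_registry())
  bad <- reg; bad$measure_id[2] <- bad$measure_id[1]
  expect_error(measure_registry(bad), "duplicate")
  bad <- reg; bad$native_min[1] <- bad$native_max[1]
  expect_error(measure_registry(bad), "native_min")
  bad <- reg; bad$orientation[1] <- "sideways"
  expect_error(measure_registry(bad), "orientation")
})

test_that("load_cohort round-trips a toy file exactly", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,visit,measure_id,value",
               "s1,KOA,baseline,NRS,6.5",
               "s1,KOA,m3,NRS,1.25",
               "s2,HOA,baseline,DN4,3"), path)
  cohort <- load_cohort(path, reg)
  rec <- cohort$records
  expect_equal(nrow(rec), 3)
  expect_equal(rec$value[rec$subject_id == "s1" & rec$visit == "baseline"], 6.5)
  expect_equal(rec$value[rec$subject_id == "s1" & rec$visit == "m3"], 1.25)
  expect_equal(rec$value[rec$subject_id == "s2"], 3)
  expect_false(any(rec$missing_flag))
})

test_that("unparseable values become flagged missing records, not drops", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,visit,measure_id,value",
               "s1,KOA,baseline,NRS,NA",
               "s1,KOA,baseline,DN4,"), path)
  cohort <- load_cohort(path, reg)
  expect_equal(nrow(cohort$records), 2)
  expect_true(all(cohort$records$missing_flag))
})

test_that("validation errors name the offending record", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,visit,measure_id,value",
               "s1,KOA,baseline,XYZ,1"), path)
  expect_error(load_cohort(path, reg), "XYZ")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,visit,measure_id,value",
               "s1,KOA,baseline,NRS,1",
               "s1,KOA,baseline,NRS,2"), path2)
  expect_error(load_cohort(path2, reg), "duplicate")

  rec <- data.frame(subject_id = c("s1", "s1"), group = c("KOA", "HOA"),
                    visit = "baseline", measure_id = c("NRS", "DN4"),
                    value = 1)
  expect_error(cohort_table(rec, reg), "group")
  rec2 <- data.frame(subject_id = "s1", group = "KOA", visit = "week2",
                     measure_id = "NRS", value = 1)
  expect_error(cohort_table(rec2, reg), "visit")
})

test_that("cohort write/load is the identity up to record order", {
  spec <- synthetic_spec(n_koa = 6L, n_hoa = 3L, rng_seed = 42)
  cohort <- generate_cohort(spec)$cohort
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(cohort, path)
  back <- load_cohort(path, cohort$registry,
                      covariates = paste0(path, ".covariates.csv"))
  key <- function(df) df[order(df$subject_id, df$visit, df$measure_id), ]
  a <- key(cohort$records); b <- key(back$records)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a, tolerance = 1e-12)
})

test_that("serialized stage outputs round-trip at full precision", {
  spec <- synthetic_spec(n_koa = 40L, n_hoa = 0L, rng_seed = 11)
  gen <- generate_cohort(spec)
  h <- harmonize_visit(gen$cohort, "baseline", "KOA")
  fm <- fit_factor_model(h$matrix, registry = default_registry())
  path <- withr::local_tempfile(fileext = ".json")
  write_results(fm, path)
  back <- read_factor_model(path)
  expect_identical(back$pattern, fm$pattern)
  expect_identical(back$weights, fm$weights)
  expect_identical(back$eigenvalues, fm$eigenvalues)

  pr <- suppressWarnings(
    permute_compare(h$matrix[1:10, 1:5], h$matrix[11:20, 1:5],
                    "mean_delta_r", reps = 10, seed = 3))
  pp <- withr::local_tempfile(fileext = ".json")
  expect_no_warning(write_results(pr, pp))
  back_pr <- read_permutation_result(pp)
  expect_identical(back_pr$draws, pr$draws)
  expect_length(back_pr$draws, 10)
  expect_identical(back_pr$probability, pr$probability)
})

test_that("network export writes GraphML and edge list with one edge set", {
  set.seed(1)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, letters[1:10]))
  net <- binarize_top(correlation_matrix(x), 0.25)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_results(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  el <- utils::read.delim(paste0(path, ".edges.tsv"))
  expect_setequal(paste(el$from, el$to), paste(net$edges$from, net$edges$to))
  expect_setequal(igraph::V(g)$community, net$communities)
})
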