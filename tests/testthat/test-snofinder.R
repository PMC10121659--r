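test_that("site tables are parsed with and without headers", {
  tf <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "accession\tposition\tptm_type",
    "P00001\t42\tS-nitrosylation"))
  df <- read_sno_sites(tf)
  expect_equal(df$accession, "P00001")
  expect_equal(df$position, 42L)
  # headerless dialect: first three columns, extras ignored
  tf2 <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "P00002\t7\tS-nitrosylation\textra\tcolumns"))
  df2 <- read_sno_sites(tf2)
  expect_equal(df2$position, 7L)
  # malformed positions are dropped with a warning
  tf3 <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "accession\tposition\tptm_type",
    "P00003\tnotanumber\tS-nitrosylation",
    "P00004\t5\tS-nitrosylation"))
  expect_warning(df3 <- read_sno_sites(tf3), "unparseable")
  expect_equal(nrow(df3), 1)
})

test_that("the discovery pipeline closes the loop with injected errors", {
  st <- synth_sites_table(3, list(missing_model = 1, non_cys = 1,
                                  out_of_range = 1), seed = 4)
  res <- suppressWarnings(run_snofinder(st$sites_path, st$model_dir))
  bk <- res$bookkeeping
  expect_equal(unname(bk["n_input_sites"]), 6)
  expect_equal(unname(bk["n_missing_model"]), 1)
  expect_equal(unname(bk["n_not_cysteine"]), 1)
  expect_equal(unname(bk["n_out_of_range"]), 1)
  expect_equal(unname(bk["n_analyzed"]), 3)
  # conservation identity
  expect_equal(unname(bk["n_input_sites"]),
               unname(bk["n_missing_model"] + bk["n_not_cysteine"] +
                        bk["n_out_of_range"] + bk["n_analyzed"]))
  # every valid protein was built with a qualifying pair
  expect_equal(sort(unique(res$pairs_all$accession)),
               sort(names(st$expected_category)))
  for (acc in names(st$expected_category))
    expect_true(st$expected_category[acc] %in%
                  res$pairs_all$category[res$pairs_all$accession == acc])
})

test_that("bookkeeping conservation holds under fuzzed site tables", {
  for (seed in 1:50) {
    set.seed(seed)
    inj <- list(missing_model = sample(0:2, 1), non_cys = sample(0:1, 1),
                out_of_range = sample(0:1, 1))
    st <- synth_sites_table(sample(1:2, 1), inj, seed = seed)
    res <- suppressWarnings(run_snofinder(st$sites_path, st$model_dir))
    bk <- res$bookkeeping
    expect_equal(unname(bk["n_input_sites"]),
                 unname(bk["n_missing_model"] + bk["n_not_cysteine"] +
                          bk["n_out_of_range"] + bk["n_analyzed"]),
                 info = paste("seed", seed))
    expect_equal(unname(bk["n_input_sites"]), nrow(st$sites))
  }
})

test_that("pair tables partition into vicinal and proximal", {
  st <- synth_sites_table(4, seed = 9)
  res <- suppressWarnings(run_snofinder(st$sites_path, st$model_dir))
  pa <- res$pairs_all
  key <- function(df) paste(df$accession, df$sno_pos, df$partner_pos,
                            df$altloc_sno, df$altloc_proxy)
  expect_setequal(c(key(res$pairs_vicinal), key(res$pairs_proximal)),
                  key(pa))
  expect_length(intersect(key(res$pairs_vicinal), key(res$pairs_proximal)),
                0)
  # the SASA filter selects a subset and is idempotent
  expect_true(all(key(res$pairs_filtered) %in% key(pa)))
  expect_true(all(res$pairs_filtered$rel_sasa_sno >= 10))
  refiltered <- res$pairs_filtered[res$pairs_filtered$rel_sasa_sno >= 10, ]
  expect_equal(nrow(refiltered), nrow(res$pairs_filtered))
})

test_that("identical inputs reproduce identical outputs", {
  st <- synth_sites_table(2, seed = 13)
  r1 <- suppressWarnings(run_snofinder(st$sites_path, st$model_dir))
  r2 <- suppressWarnings(run_snofinder(st$sites_path, st$model_dir))
  expect_identical(r1$pairs_all, r2$pairs_all)
  expect_identical(r1$bookkeeping, r2$bookkeeping)
})

test_that("empty site tables yield empty outputs with zeroed bookkeeping", {
  dir <- withr::local_tempdir()
  sites <- data.frame(accession = character(0), position = integer(0),
                      ptm_type = character(0))
  res <- run_snofinder(sites, dir)
  expect_equal(nrow(res$pairs_all), 0)
  expect_equal(unname(res$bookkeeping["n_input_sites"]), 0)
  expect_equal(summarize_dataset(res)$n_proteins_with_partner, 0)
})

test_that("per-protein rollups count vicinal/proximal/both and multi-SNO", {
  pa <- data.frame(
    accession = c("A", "B", "B", "C", "C"),
    sno_pos = c(10L, 10L, 10L, 10L, 40L),
    partner_pos = c(13L, 13L, 40L, 13L, 44L),
    category = c("vicinal", "vicinal", "proximal", "vicinal", "vicinal"),
    rel_sasa_sno = 50, stringsAsFactors = FALSE)
  res <- structure(list(pairs_all = pa), class = "snofinder_result")
  s <- summarize_dataset(res)
  expect_equal(s$n_proteins_with_partner, 3)
  expect_equal(s$n_vicinal_only, 2)
  expect_equal(s$n_both, 1)
  expect_equal(s$n_proximal_only, 0)
  expect_equal(s$n_single_sno, 2)
  expect_equal(s$n_multi_sno, 1)
})

test_that("results are written as CSV tables plus bookkeeping JSON", {
  st <- synth_sites_table(1, seed = 21)
  res <- suppressWarnings(run_snofinder(st$sites_path, st$model_dir))
  outdir <- withr::local_tempdir()
  write_snofinder_result(res, outdir)
  expect_true(all(file.exists(file.path(outdir, c(
    "pairs_all.csv", "pairs_vicinal.csv", "pairs_proximal.csv",
    "pairs_filtered.csv", "bookkeeping.json")))))
  bk <- jsonlite::read_json(file.path(outdir, "bookkeeping.json"))
  expect_equal(bk$n_input_sites, 1)
})
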