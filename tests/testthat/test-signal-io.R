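test_that("CSV records round-trip signal, fs, labels and ground truth", {
  rec <- generate_record(demo_class_specs(1, noise_sd = 0.05)[[1]], seed = 3)
  path <- file.path(tempdir(), "roundtrip.csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-12)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$superclass, rec$superclass)
  expect_identical(back$truth_rpeaks, rec$truth_rpeaks)
  expect_equal(ncol(back$signal), 5000L)
})

test_that("reading rejects wrong channel counts and missing files", {
  path <- file.path(tempdir(), "threelead.csv")
  utils::write.table(matrix(rnorm(300), ncol = 3), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = 500), sub("csv$", "json", path),
                       auto_unbox = TRUE)
  expect_error(read_record(path), "12 channels")
  expect_error(read_record(file.path(tempdir(), "nope.csv")), "no such file")
  expect_error(ecg_record(matrix(0, 3, 10), 500), "12 leads")
})

test_that("WFDB format-16 pairs round-trip within quantization error", {
  rec <- generate_record(demo_class_specs(1, noise_sd = 0)[[1]], seed = 4)
  base <- file.path(tempdir(), "wfdbrec")
  write_record(rec, base, format = "wfdb")
  back <- read_record(paste0(base, ".hea"))
  expect_equal(dim(back$signal), dim(rec$signal))
  expect_identical(back$fs, rec$fs)
  # gain 1000 adu/mV quantizes at 0.0005 mV
  expect_lt(max(abs(back$signal - rec$signal)), 1e-3)
})

test_that("label catalog validates the subclass-to-superclass mapping", {
  cat5 <- default_catalog()
  expect_length(cat5$superclasses, 5L)
  expect_length(cat5$subclasses, 20L)
  expect_true(all(cat5$subclass_to_superclass %in% cat5$superclasses))
  expect_error(label_catalog("A", c("a1", "a2"), c(a1 = "A")),
               "every subclass")
  expect_error(label_catalog("A", "b1", c(b1 = "B")), "unknown superclass")
})

toy_statements <- data.frame(
  code = c("c1", "c2", "c3", "c4"),
  superclass = c("NORM", "MI", "MI", "STTC"),
  subclass = c("NORM_1", "MI_1", "MI_2", "STTC_1"))

test_that("confidence and ambiguity filters drop the stated records", {
  md <- data.frame(
    record_id = c("r1", "r2", "r3", "r4", "r5", "r5", "r6"),
    code = c("zz", "c1", "c1", "c2", "c1", "c2", "c3"),
    likelihood = c(100, 50, 100, 100, 100, 100, 100))
  # r1 unlabeled (non-diagnostic code), r2 at 50% confidence,
  # r5 resolves to two superclasses: all removed
  out <- filter_ptbxl(md, toy_statements, min_subclass_size = 1L)
  expect_setequal(out$record_id, c("r3", "r4", "r6"))
  expect_equal(out$superclass[out$record_id == "r4"], "MI")
})

test_that("subclasses below the size threshold are removed in one pass", {
  md <- data.frame(
    record_id = c(sprintf("a%02d", 1:19), sprintf("b%02d", 1:25)),
    code = c(rep("c1", 19), rep("c2", 25)),
    likelihood = 100)
  out <- filter_ptbxl(md, toy_statements, min_subclass_size = 20L)
  expect_setequal(unique(out$subclass), "MI_1")
  expect_equal(nrow(out), 25L)
})

test_that("the record filter is idempotent", {
  md <- data.frame(
    record_id = c(sprintf("a%d", 1:5), sprintf("b%d", 1:3), "x", "x"),
    code = c(rep("c1", 5), rep("c2", 3), "c1", "c4"),
    likelihood = c(rep(100, 8), 100, 100))
  out1 <- filter_ptbxl(md, toy_statements, min_subclass_size = 3L)
  md2 <- md[md$record_id %in% out1$record_id, , drop = FALSE]
  out2 <- filter_ptbxl(md2, toy_statements, min_subclass_size = 3L)
  expect_identical(out1, out2)
  # surviving assignments respect the statement map
  expect_true(all(out1$superclass ==
    toy_statements$superclass[match(out1$subclass,
                                    toy_statements$subclass)]))
})

test_that("the filter demands the documented columns", {
  expect_error(filter_ptbxl(data.frame(record_id = "r"), toy_statements),
               "columns")
  expect_error(filter_ptbxl(
    data.frame(record_id = "r", code = "c1", likelihood = 100),
    data.frame(code = "c1")), "columns")
})
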