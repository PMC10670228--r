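# Inspection sessions: record assembly, lookup, serialization.

make_session <- function(n = 3) {
  emb <- data.frame(id = sprintf("img%02d", seq_len(n)),
                    x = seq_len(n) * 1.0, y = rep(0, n),
                    split = rep(c("train", "test"), length.out = n),
                    label = rep(grade_levels(), length.out = n),
                    stringsAsFactors = FALSE)
  preds <- data.frame(id = emb$id,
                      IA = c(0.6604, 0.1, 0.2)[seq_len(n)],
                      MIA = c(0.0, 0.8, 0.3)[seq_len(n)],
                      NOR = c(0.3396, 0.1, 0.5)[seq_len(n)],
                      stringsAsFactors = FALSE)
  meta <- data.frame(id = emb$id,
                     name = sprintf("Synthetic Patient %d", seq_len(n)),
                     chart_number = sprintf("C%05d", seq_len(n)),
                     gender = rep(c("F", "M"), length.out = n),
                     sample_number = seq_len(n),
                     volume_number = seq_len(n),
                     n_bscans = rep(400L, n),
                     stringsAsFactors = FALSE)
  build_session(emb, preds, meta,
                image_refs = setNames(sprintf("images/%s.tif", emb$id), emb$id),
                cam_refs = setNames(sprintf("cams/%s.png", emb$id), emb$id),
                model_info = list(model = "attention-resnet", version = "0.1.0"))
}

test_that("sessions join every embedding point to exactly one record", {
  s <- make_session()
  expect_length(s$records, 3)
  expect_setequal(names(s$records), sprintf("img%02d", 1:3))
  rec <- s$records[["img01"]]
  expect_equal(rec$probabilities,
               c(IA = 0.6604, MIA = 0, NOR = 0.3396))
  expect_equal(rec$predicted_class, "IA")
  expect_equal(rec$metadata$name, "Synthetic Patient 1")
  expect_equal(rec$image_ref, "images/img01.tif")
})

test_that("missing or dangling predictions are named in the error", {
  emb <- data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 0))
  preds <- data.frame(id = "a", IA = 1, MIA = 0, NOR = 0)
  expect_error(build_session(emb, preds), "b")
  preds2 <- rbind(preds, data.frame(id = c("b", "zz"),
                                    IA = c(1, 1), MIA = 0, NOR = 0))
  expect_error(build_session(emb, preds2), "zz")
  bad <- data.frame(id = c("a", "b"), IA = c(0.5, 1), MIA = c(0.2, 0),
                    NOR = c(0.2, 0))
  expect_error(build_session(emb, bad), "sum to 1")
})

test_that("missing metadata fields become explicit NA markers", {
  emb <- data.frame(id = "a", x = 0, y = 0)
  preds <- data.frame(id = "a", IA = 1, MIA = 0, NOR = 0)
  s <- build_session(emb, preds, metadata = data.frame(id = "a", gender = "F"))
  expect_equal(s$records[["a"]]$metadata$gender, "F")
  expect_true(is.na(s$records[["a"]]$metadata$chart_number))
})

test_that("point lookup works by id and by nearest coordinates", {
  s <- make_session()
  expect_equal(lookup_point(s, id = "img02")$id, "img02")
  expect_equal(lookup_point(s, at = c(2.0, 0))$id, "img02")
  expect_equal(lookup_point(s, at = c(2.4, 0))$id, "img02")
  # exact tie between img01 (x=1) and img02 (x=2): earlier id wins
  expect_equal(lookup_point(s, at = c(1.5, 0))$id, "img01")
  expect_error(lookup_point(s, id = "nope"), "no record")
  expect_error(lookup_point(s), "exactly one")
  expect_error(lookup_point(s, id = "a", at = c(0, 0)), "exactly one")
})

test_that("displayed probability strings total 100 percent", {
  s <- make_session()
  str1 <- format_probabilities(s$records[["img01"]]$probabilities)
  expect_equal(str1, "IA: 66.04% and NOR: 33.96%")
  for (rec in s$records) {
    shown <- as.numeric(gsub("%", "", regmatches(
      format_probabilities(rec$probabilities),
      gregexpr("[0-9.]+%", format_probabilities(rec$probabilities)))[[1]]))
    expect_lt(abs(sum(shown) - 100), 0.1)
  }
})

test_that("sessions round-trip through JSON losslessly", {
  s <- make_session()
  dir <- withr::local_tempdir()
  export_session(s, dir)
  s2 <- import_session(dir)
  expect_equal(s2$records, s$records)
  expect_equal(s2$embedding, s$embedding)
  expect_equal(s2$model_info, s$model_info)
  expect_identical(s2$schema_version, s$schema_version)
})

test_that("corrupt manifests and foreign schema versions are rejected whole", {
  dir <- withr::local_tempdir()
  writeLines("{ not json", file.path(dir, "session.json"))
  expect_error(import_session(dir), "corrupt")

  s <- make_session()
  dir2 <- withr::local_tempdir()
  export_session(s, dir2)
  j <- readLines(file.path(dir2, "session.json"))
  writeLines(gsub("\"1.0\"", "\"9.9\"", j, fixed = TRUE),
             file.path(dir2, "session.json"))
  expect_error(import_session(dir2), "migrate")
  expect_error(import_session(file.path(dir2, "missing")), "no session")
})

test_that("an empty session is valid and survives a round trip", {
  emb <- data.frame(id = character(0), x = numeric(0), y = numeric(0))
  preds <- data.frame(id = character(0), IA = numeric(0), MIA = numeric(0),
                      NOR = numeric(0))
  s <- build_session(emb, preds)
  expect_length(s$records, 0)
  dir <- withr::local_tempdir()
  export_session(s, dir)
  expect_length(import_session(dir)$records, 0)
  expect_error(lookup_point(s, id = "x"), "no records")
})

test_that("lookup does not mutate the session (read-only interface)", {
  s <- make_session()
  before <- s$records
  invisible(lookup_point(s, at = c(10, 10)))
  invisible(lookup_point(s, id = "img03"))
  expect_identical(s$records, before)
})
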