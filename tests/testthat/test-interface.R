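cli_quiet <- function(args) suppressMessages(mhn_cli(args))

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("CSV datasets are read with validation and id auto-detection", {
  f <- write_lines_tmp(c("TP53,KRAS,EGFR", "1,0,1", "0,0,0"))
  d <- read_dataset(f)
  expect_equal(dim(d), c(2, 3))
  expect_identical(colnames(d), c("TP53", "KRAS", "EGFR"))
  expect_null(rownames(d))

  fid <- write_lines_tmp(c("sample_id,TP53,KRAS", "P01,1,0", "P02,0,1"))
  did <- read_dataset(fid)
  expect_identical(rownames(did), c("P01", "P02"))
  expect_equal(unname(did[1, ]), c(1L, 0L))
  # the same file read with id detection disabled fails on the text cell
  expect_error(read_dataset(fid, id_column = "no"), "non-binary")

  fbad <- write_lines_tmp(c("A,B", "1,2", "0,0"))
  expect_error(read_dataset(fbad), "non-binary value '2' at row 1, column 'B'")

  frag <- write_lines_tmp(c("A,B", "1,0", "1"))
  expect_error(read_dataset(frag), "ragged")

  fdup <- write_lines_tmp(c("A,A", "1,0"))
  expect_error(read_dataset(fdup), "unique")

  fwide <- write_lines_tmp(c(paste(paste0("E", 1:40), collapse = ","),
                             paste(c(rep(1, 33), rep(0, 7)), collapse = ",")))
  expect_error(read_dataset(fwide), "32 active events")
})

test_that("dataset write/read round trip is cell-identical", {
  m <- random_model(3, 91)
  d <- sample_mhn(m, 30, seed = 91)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  d2 <- read_dataset(f)
  expect_identical(d2, d)
  # canonical file: write(read(f)) reproduces the file text
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("heatmaps display multiplicative effects with base rates separate", {
  m0 <- mhn_model(matrix(0, 3, 2), events = c("A", "B"))
  p <- render_heatmap(m0)
  expect_s3_class(p, "ggplot")
  lab <- p$data$label[p$data$label != ""]
  expect_true(all(lab == "1.00")) # exp(0) everywhere
  expect_true("observation" %in% p$data$row)
  expect_true("base rate" %in% p$data$col)
  # diagonal of the interaction matrix is blank
  expect_identical(p$data$label[p$data$row == "A" & p$data$col == "A"], "")

  th <- matrix(0, 3, 2)
  th[3, 1] <- log(10.91)
  m1 <- mhn_model(th, events = c("A", "B"))
  p1 <- render_heatmap(m1)
  expect_identical(
    p1$data$label[p1$data$row == "observation" & p1$data$col == "A"], "10.91")

  # classic models render no observation row
  pc <- render_heatmap(mhn_model(th, events = c("A", "B"), kind = "classic"))
  expect_false("observation" %in% pc$data$row)

  f <- withr::local_tempfile(fileext = ".png")
  render_heatmap(m1, path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("the CLI round-trips sample -> train -> reconstruct -> tree", {
  dir <- withr::local_tempdir()
  model0 <- file.path(dir, "true.json")
  write_mhn(planted_model(), model0)
  data_csv <- file.path(dir, "cohort.csv")
  trained <- file.path(dir, "trained.json")

  expect_equal(cli_quiet(c("sample", "--model", model0, "--n", "300",
                         "--seed", "5", "--out", data_csv,
                         "--histories", file.path(dir, "hist.json"))), 0L)
  expect_true(file.exists(data_csv) && file.exists(file.path(dir, "hist.json")))

  expect_equal(cli_quiet(c("train", "--data", data_csv, "--out", trained,
                         "--penalty", "l1", "--strength", "0.05")), 0L)
  mt <- read_mhn(trained)
  expect_identical(mt$kind, "observation_aware")
  expect_identical(mt$events, paste0("E", 1:5))

  classic <- file.path(dir, "classic.json")
  expect_equal(cli_quiet(c("train", "--data", data_csv, "--out", classic,
                         "--kind", "classic", "--strength", "0.05")), 0L)
  mc <- read_mhn(classic)
  expect_identical(mc$kind, "classic")
  expect_true(all(mc$log_theta[6, ] == 0))

  orders_csv <- file.path(dir, "orders.csv")
  expect_equal(cli_quiet(c("reconstruct", "--model", trained,
                         "--data", data_csv, "--out", orders_csv)), 0L)
  tab <- utils::read.csv(orders_csv)
  expect_equal(nrow(tab), 300)

  dot <- file.path(dir, "tree.dot")
  expect_equal(cli_quiet(c("tree", "--model", trained, "--data", data_csv,
                         "--min-count", "3", "--dot", dot,
                         "--json", file.path(dir, "tree.json"))), 0L)
  expect_match(readLines(dot)[1], "digraph")

  png <- file.path(dir, "heat.png")
  expect_equal(cli_quiet(c("plot", "--model", trained, "--out", png)), 0L)
  expect_true(file.size(png) > 0)
})

test_that("the tree command drops genotypes below the patient threshold", {
  dir <- withr::local_tempdir()
  th <- matrix(0, 3, 2); th[2, 1] <- 2; th[1, 2] <- -2
  m <- mhn_model(th, events = c("A", "B"))
  model_f <- file.path(dir, "m.json")
  write_mhn(m, model_f)
  d <- rbind(matrix(rep(c(1L, 0L), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 2), 2, 2, byrow = TRUE))
  colnames(d) <- c("A", "B")
  data_f <- file.path(dir, "d.csv")
  write_dataset(d, data_f)
  dot <- file.path(dir, "t.dot")
  expect_equal(cli_quiet(c("tree", "--model", model_f, "--data", data_f,
                         "--min-count", "3", "--dot", dot)), 0L)
  txt <- paste(readLines(dot), collapse = "\n")
  expect_false(grepl('label="B"', txt)) # only 2 patients carry {B}
  expect_true(grepl('label="A"', txt))
})

test_that("CLI usage errors exit with code 2", {
  expect_equal(suppressMessages(mhn_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(mhn_cli(c("train", "--out", "x.json"))), 2L)
  expect_equal(suppressMessages(
    cli_quiet(c("sample", "--model", "nope.json", "--n", "5",
              "--seed", "1", "--out", "x.csv"))), 2L)
  expect_equal(suppressMessages(mhn_cli(character(0))), 0L) # usage text
})

test_that("seeded CLI runs are byte-identical", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m <- planted_model()
  run <- function(dir) {
    model0 <- file.path(dir, "m.json")
    write_mhn(m, model0)
    dcsv <- file.path(dir, "d.csv")
    cli_quiet(c("sample", "--model", model0, "--n", "150", "--seed", "11",
              "--out", dcsv))
    cli_quiet(c("train", "--data", dcsv, "--out", file.path(dir, "fit.json"),
              "--strength", "0.05"))
  }
  suppressMessages({run(dir1); run(dir2)})
  for (f in c("d.csv", "fit.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
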