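test_that("task ids are deterministic and payload-sensitive", {
  p1 <- list(op = "knockout", ko1 = "FERM", ko2 = "none")
  p2 <- list(ko2 = "none", op = "knockout", ko1 = "FERM") # field order
  p3 <- list(op = "knockout", ko1 = "FERMX", ko2 = "none")
  expect_identical(task_id(p1), task_id(p1))
  expect_identical(task_id(p1), task_id(p2)) # canonicalized
  expect_false(task_id(p1) == task_id(p3))
  expect_match(task_id(p1), "^[0-9a-f]{8}$")
})

test_that("run_tasks executes, aggregates and isolates failures", {
  tasks <- make_tasks(lapply(1:10, function(i) list(i = i)))
  fn <- function(p) {
    if (p$i == 7) stop("LP infeasible (synthetic)")
    list(i = p$i, sq = p$i^2)
  }
  run <- run_tasks(tasks, fn)
  expect_equal(run$report$total, 10)
  expect_equal(run$report$done, 9)
  expect_equal(run$report$failed, 1)
  expect_equal(run$report$pending, 0)
  bad <- run$results[run$results$status == "failed", ]
  expect_match(bad$error, "infeasible")
  expect_equal(sort(as.numeric(run$results$sq[run$results$status == "done"])),
               sort((1:10)[-7]^2))
})

test_that("worker counts do not change the sorted results", {
  tasks <- make_tasks(lapply(1:10, function(i) list(i = i)))
  fn <- function(p) list(i = p$i, v = p$i * 3)
  r1 <- run_tasks(tasks, fn, workers = 1)$results
  r4 <- run_tasks(tasks, fn, workers = 4)$results
  expect_identical(r1, r4)
})

test_that("checkpointed runs resume exactly where they stopped", {
  dir <- withr::local_tempdir()
  ck <- file.path(dir, "checkpoint.csv")
  tasks <- make_tasks(lapply(1:10, function(i) list(i = i)))
  counter_file <- file.path(dir, "count")
  fn <- function(p) {
    n <- if (file.exists(counter_file))
      as.integer(readLines(counter_file)) else 0L
    writeLines(as.character(n + 1L), counter_file)
    list(i = p$i, v = p$i * 2)
  }
  # first run: only 5 tasks "survive" (simulate a kill after 5)
  run_tasks(tasks[1:5], fn, checkpoint = ck)
  expect_equal(as.integer(readLines(counter_file)), 5L)
  # restart with the full task list: exactly the 5 remaining execute
  full <- run_tasks(tasks, fn, checkpoint = ck)
  expect_equal(as.integer(readLines(counter_file)), 10L)
  expect_equal(full$report$done, 10)
  expect_equal(nrow(full$results), 10)
})

test_that("the CLI drives the whole stack from files", {
  dir <- withr::local_tempdir()
  suite <- file.path(dir, "suite")
  expect_equal(ferm_cli(c("fixtures", "--out-dir", suite,
                          "--log-level", "quiet")), 0L)
  out <- file.path(dir, "out")
  code <- ferm_cli(c("simulate",
                     "--model", file.path(suite, "toyA.tsv"),
                     "--media", file.path(suite, "media_M1.csv"),
                     "--registry", file.path(suite, "registry.csv"),
                     "--target", "etoh", "--oxygen", "anaerobic",
                     "--out-dir", out, "--log-level", "quiet"))
  expect_equal(code, 0L)
  d <- utils::read.csv(file.path(out, "result.csv"),
                       stringsAsFactors = FALSE)
  expect_equal(d$yield_max_pct[d$step == "total"], 41.911, tolerance = 1e-3)

  code2 <- ferm_cli(c("two-step",
                      "--model", file.path(suite, "toyA.tsv"),
                      "--model2", file.path(suite, "toyB.tsv"),
                      "--media", file.path(suite, "media_M2.csv"),
                      "--registry", file.path(suite, "registry.csv"),
                      "--target", "etoh", "--out-dir", out,
                      "--log-level", "quiet"))
  expect_equal(code2, 0L)
  d2 <- utils::read.csv(file.path(out, "result.csv"),
                        stringsAsFactors = FALSE)
  expect_equal(d2$yield_max_pct[d2$step == "total"], 38.078,
               tolerance = 1e-3)
})

test_that("the CLI knockout scan emits the full grid and a JSON report", {
  dir <- withr::local_tempdir()
  suite <- file.path(dir, "suite")
  write_toy_suite(suite)
  out <- file.path(dir, "out")
  code <- ferm_cli(c("knockout-scan",
                     "--model", file.path(suite, "toyA.tsv"),
                     "--model2", file.path(suite, "toyB.tsv"),
                     "--media", file.path(suite, "media_M2.csv"),
                     "--registry", file.path(suite, "registry.csv"),
                     "--target", "etoh", "--workers", "2",
                     "--out-dir", out, "--log-level", "quiet"))
  expect_equal(code, 0L)
  d <- utils::read.csv(file.path(out, "knockout_scan.csv"),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(d), 16) # (3+1)(3+1)
  rep <- jsonlite::fromJSON(file.path(out, "run_report.json"))
  expect_equal(rep$total, 16)
  expect_equal(rep$failed, 0)
})

test_that("CLI plan prints the enumeration counts", {
  txt <- capture.output(
    code <- ferm_cli(c("plan", "--media", "3", "--targets", "5",
                       "--organisms", "4", "--conditions", "2")))
  expect_equal(code, 0L)
  expect_true(any(grepl("configurations: 240", txt)))
  expect_true(any(grepl("tasks: 480", txt)))
})

test_that("a JSON config supplies options that flags can override", {
  dir <- withr::local_tempdir()
  suite <- file.path(dir, "suite")
  write_toy_suite(suite)
  cfg <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(model = file.path(suite, "toyA.tsv"),
         media = file.path(suite, "media_M1.csv"),
         registry = file.path(suite, "registry.csv"),
         target = "etoh", `log-level` = "quiet",
         `out-dir` = file.path(dir, "from_config")),
    cfg, auto_unbox = TRUE)
  code <- ferm_cli(c("simulate", "--config", cfg))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "from_config", "result.csv")))
  # flag overrides the config's out-dir
  code2 <- ferm_cli(c("simulate", "--config", cfg,
                      "--out-dir", file.path(dir, "flagged")))
  expect_equal(code2, 0L)
  expect_true(file.exists(file.path(dir, "flagged", "result.csv")))
})

test_that("bad arguments yield a usage message and exit code 2", {
  expect_output(code <- ferm_cli(character(0)), "usage")
  expect_equal(code, 2L)
  expect_output(code2 <- ferm_cli("not-a-subcommand"), "usage")
  expect_equal(code2, 2L)
  suppressMessages(code3 <- ferm_cli(c("simulate", "--target")))
  expect_equal(code3, 2L)
})
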