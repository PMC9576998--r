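test_that("read_feature_table parses delimited text and validates rows", {
  path <- write_temp_table(c(
    "subject,session,phase,label,f01,f02",
    "S0,session1,task,low,1.0,2.0",
    "S0,session2,task,high,1.5,2.5",
    "S1,session1,task,low,0.5,0.1",
    "S1,session2,task,high,0.7,0.2"))
  tab <- read_feature_table(path)
  expect_equal(nrow(tab), 4)
  expect_equal(feature_cols(tab), c("f01", "f02"))
  expect_equal(tab$f01, c(1.0, 1.5, 0.5, 0.7))

  tsv <- write_temp_table(c(
    "subject\tsession\tphase\tlabel\tf01",
    "S0\tsession1\ttask\tlow\t1",
    "S0\tsession2\ttask\thigh\t2"))
  expect_equal(nrow(read_feature_table(tsv)), 2)
})

test_that("baseline rows may lack labels but task rows may not", {
  ok <- write_temp_table(c(
    "subject,session,phase,label,f01",
    "S0,session1,task,low,1",
    "S0,session2,task,high,2",
    "S0,session1,baseline1,,0.5"))
  tab <- read_feature_table(ok)
  expect_true(is.na(tab$label[tab$phase == "baseline1"]))

  bad <- write_temp_table(c(
    "subject,session,phase,label,f01",
    "S0,session1,task,low,1",
    "S0,session2,task,,2"))
  expect_error(read_feature_table(bad), "label")
})

test_that("schema errors name the offending column and bad cells the row", {
  no_subj <- write_temp_table(c("session,phase,label,f01",
                                "session1,task,low,1"))
  expect_error(read_feature_table(no_subj), "subject")

  bad_num <- write_temp_table(c(
    "subject,session,phase,label,f01",
    "S0,session1,task,low,1",
    "S0,session2,task,high,oops"))
  expect_error(read_feature_table(bad_num), "f01")

  mapped <- write_temp_table(c(
    "participant,session,phase,label,f01",
    "S0,session1,task,low,1",
    "S0,session2,task,high,2"))
  tab <- read_feature_table(mapped, schema = c(subject = "participant"))
  expect_equal(tab$subject, c("S0", "S0"))
  expect_error(read_feature_table(mapped, schema = c(subject = "nope")),
               "nope")
})

test_that("labels are derived from sessions when no label column exists", {
  path <- write_temp_table(c(
    "subject,session,phase,f01",
    "S0,sessB,task,1",
    "S0,sessA,task,2",
    "S0,sessA,baseline1,3"))
  tab <- read_feature_table(path)
  expect_equal(tab$label, c("high", "low", NA))
})

test_that("partition_by_subject orders subjects lexicographically and preserves rows", {
  tab <- make_small_table()
  tab <- tab[sample(nrow(tab)), ]  # scrambled input order
  doms <- partition_by_subject(tab, "task")
  expect_equal(names(doms), c("S0", "S1"))
  expect_s3_class(doms[[1]], "domain_sample")
  # union of rows equals the phase-filtered table, per subject
  for (s in names(doms)) {
    rows <- tab[tab$phase == "task" & tab$subject == s, feature_cols(tab)]
    expect_equal(sort(as.matrix(rows)[, 1]), sort(doms[[s]]$X[, 1]))
    expect_equal(length(doms[[s]]$y), nrow(rows))
  }
  expect_error(partition_by_subject(tab[tab$phase == "task", ], "baseline1"),
               "baseline1")
})

test_that("partition errors list subjects missing the requested phase", {
  tab <- make_small_table()
  tab2 <- tab[!(tab$subject == "S1" & tab$phase == "baseline2"), ]
  expect_error(partition_by_subject(tab2, "baseline2"), "S1")
})

test_that("subsample draws exactly n_per_cell rows per cell, deterministically", {
  tab <- make_small_table(n_cell = 40)
  pro <- sampling_protocol(n_per_cell = 15, n_repetitions = 3, base_seed = 10)
  s1 <- subsample(tab, pro, 1)
  s1b <- subsample(tab, pro, 1)
  s2 <- subsample(tab, pro, 2)
  expect_identical(s1, s1b)
  expect_false(identical(s1, s2))
  counts <- dplyr::count(s1[s1$phase == "task", ], subject, session)
  expect_true(all(counts$n == 15))
  # baseline rows pass through unchanged
  expect_identical(s1[s1$phase != "task", ], tab[tab$phase != "task", ])
  # pooling repetitions never invents rows
  pooled <- dplyr::bind_rows(s1, s2)
  expect_true(all(do.call(paste, pooled) %in% do.call(paste, tab)))
})

test_that("subsample returns full cells when n_per_cell equals the cell size", {
  tab <- make_small_table(n_cell = 12)
  pro <- sampling_protocol(n_per_cell = 12, n_repetitions = 1)
  out <- subsample(tab, pro, 1)
  expect_identical(out, tab)
  expect_error(subsample(tab, sampling_protocol(n_per_cell = 13), 1),
               "fewer than")
})

test_that("split_disjoint stratifies by label with exact disjoint union", {
  dom <- make_rule_domain("S0", 100, sep = 2, seed = 4)
  parts <- split_disjoint(dom, 0.5, seed = 9)
  expect_equal(nrow(parts$train$X) + nrow(parts$test$X), 100)
  key <- function(d) apply(d$X, 1, paste, collapse = "|")
  expect_length(intersect(key(parts$train), key(parts$test)), 0)
  expect_setequal(c(key(parts$train), key(parts$test)), key(dom))
  expect_equal(sum(parts$train$y), round(sum(dom$y) * 0.5), tolerance = 0.51)

  tiny <- domain_sample("T", matrix(1:8, 4, 2), c(0L, 0L, 1L, 1L))
  p <- split_disjoint(tiny, 0.5, seed = 1)
  expect_equal(sort(p$train$y), c(0L, 1L))
  expect_equal(sort(p$test$y), c(0L, 1L))

  single <- domain_sample("U", matrix(1:8, 4, 2), c(0L, 0L, 0L, 0L))
  expect_error(split_disjoint(single, 0.5, 1), ">= 2")
})
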