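test_that("response normalization strips fillers and unifies plurals", {
  expect_equal(normalize_response("used for a vase"), "vase")
  expect_equal(normalize_response("Vases"), "vase")
  expect_equal(normalize_response("vase"), "vase")
  # idempotence on a batch of decorated responses
  raw <- c("Used for a doorstop", "paperweights", "it can be a toy boat",
           "candle holders")
  once <- normalize_response(raw)
  expect_equal(normalize_response(once), once)
  expect_equal(once, c("doorstop", "paperweight", "toy boat",
                       "candle holder"))
  # emptied-out responses surface as "" (invalid)
  expect_equal(normalize_response("used for"), "")
})

test_that("statistical infrequency matches the worked example", {
  # 8 occurrences of "vase" among 20 responses for one object -> 0.60
  texts <- c(rep("vase", 8), sprintf("other%02d", 1:12))
  tab <- make_responses(sprintf("P%02d", 1:20), "brick", texts)
  fb <- score_fb_originality(tab)
  expect_equal(unique(fb$per_response$infrequency[
    fb$per_response$normalized_text == "vase"]), 0.60)
  # a unique response among N scores 1 - 1/N
  expect_equal(fb$per_response$infrequency[
    fb$per_response$normalized_text == "other01"], 1 - 1 / 20)
  # all responses identical -> infrequency 0 for each
  same <- make_responses(sprintf("P%02d", 1:20), "brick",
                         rep("vase", 20))
  fb0 <- score_fb_originality(same)
  expect_true(all(fb0$per_response$infrequency == 0))
  expect_true(all(fb0$per_participant$fb_originality == 0))
})

test_that("FB originality is order-invariant and bounded in [0, 1)", {
  set.seed(1)
  tab <- make_responses(sample(sprintf("P%02d", 1:10), 60, TRUE),
                        sample(c("brick", "hat"), 60, TRUE),
                        sample(sprintf("idea%d", 1:12), 60, TRUE))
  a <- score_fb_originality(tab)$per_participant
  perm <- tab[sample(nrow(tab)), ]
  b <- score_fb_originality(perm)$per_participant
  expect_equal(a[order(a$participant_id), ],
               b[order(b$participant_id), ], ignore_attr = TRUE)
  expect_true(all(a$fb_originality >= 0 & a$fb_originality < 1))
})

test_that("flexibility and fluency follow the category/count definitions", {
  # 3 distinct categories on each of 5 objects -> flexibility 3.0
  objs <- sprintf("obj%d", 1:5)
  tab <- do.call(rbind, lapply(objs, function(o)
    make_responses("P01", o, sprintf("%s r%d", o, 1:6),
                   category_label = rep(c("a", "b", "c"), 2))))
  ff <- score_flexibility_fluency(tab)
  expect_equal(ff$flexibility, 3.0)
  expect_equal(ff$fluency, 30L)
  # all responses in one category per object -> flexibility 1.0
  tab1 <- do.call(rbind, lapply(objs, function(o)
    make_responses("P01", o, sprintf("%s r%d", o, 1:4),
                   category_label = "only")))
  expect_equal(score_flexibility_fluency(tab1)$flexibility, 1.0)
  # 12 valid + 2 invalid responses -> fluency 12
  tab2 <- make_responses("P01", "obj1",
                         c(sprintf("r%d", 1:12), "", ""))
  expect_equal(score_flexibility_fluency(tab2)$fluency, 12L)
  # duplicating a response in an already-used category leaves
  # flexibility unchanged
  dup <- rbind(tab, tab[1, ])
  expect_equal(score_flexibility_fluency(dup)$flexibility, 3.0)
  # flexibility never exceeds fluency / n_objects
  expect_lte(ff$flexibility, ff$fluency / 5)
})

test_that("exclusion accounting balances valid, invalid and total rows", {
  tab <- make_responses(rep(c("P01", "P02"), each = 5), "obj1",
                        c(sprintf("r%d", 1:4), "", sprintf("s%d", 1:3),
                          "", ""))
  res <- score_aut(tab)
  expect_equal(sum(res$participants$fluency) + res$n_invalid, nrow(tab))
})

test_that("rater-based originality averages judges then ideas", {
  tab <- make_responses("P01", "obj1", c("r1", "r2", "r3"),
                        rater1 = c(3, 2, 4), rater2 = c(5, 2, 4))
  rb <- score_rb_originality(tab)
  expect_equal(rb$per_idea$idea_score, c(4, 2, 4))
  expect_equal(rb$per_participant$rb_originality, 10 / 3)
  # averaging is exchangeable over raters
  swapped <- tab
  swapped$rater1_score <- tab$rater2_score
  swapped$rater2_score <- tab$rater1_score
  expect_equal(score_rb_originality(swapped)$per_participant,
               rb$per_participant)
  # all (1,1) ideas -> participant score exactly 1; bounds hold
  ones <- make_responses("P01", "obj1", c("r1", "r2"), rater1 = 1,
                         rater2 = 1)
  expect_equal(score_rb_originality(ones)$per_participant$rb_originality, 1)
  # consensus override replaces the mean where present
  tab$consensus_score <- c(NA, NA, 5)
  rb2 <- score_rb_originality(tab)
  expect_equal(rb2$per_idea$idea_score, c(4, 2, 5))
  # missing ratings excluded with a warning
  tab$rater2_score[1] <- NA
  expect_warning(rb3 <- score_rb_originality(tab), "missing")
  expect_equal(nrow(rb3$per_idea), 2)
})

test_that("ICC(2,k) matches its definitions and an aov cross-check", {
  # identical rater columns -> 1
  m <- cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(1, 2, 3, 4, 5))
  expect_equal(compute_icc(m)$icc, 1.0)
  # independent shuffle -> near 0 at n = 1000
  set.seed(3)
  r1 <- rnorm(1000)
  m2 <- cbind(r1, sample(r1))
  expect_lt(abs(compute_icc(m2)$icc), 0.1)
  # zero between-idea variance is undefined, with warning
  expect_warning(res <- compute_icc(cbind(rep(2, 5), rep(2, 5))),
                 "undefined")
  expect_true(is.na(res$icc))
  # dual route: closed form vs aov mean squares
  set.seed(8)
  q <- rnorm(40, 3, 0.8)
  mm <- cbind(q + rnorm(40, 0, 0.4), q + rnorm(40, 0, 0.4))
  long <- data.frame(y = c(mm), idea = factor(rep(1:40, 2)),
                     rater = factor(rep(1:2, each = 40)))
  ms <- summary(aov(y ~ idea + rater, data = long))[[1]][, "Mean Sq"]
  icc_aov <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / 40)
  expect_equal(compute_icc(mm)$icc, icc_aov, tolerance = 1e-10)
})
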