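#' Default stop-phrase list for response normalization
#'
#' Filler phrases and articles removed from raw Alternative Uses Task
#' responses before equivalence matching. The shipped plain-text list can
#' be extended by curators and passed back in.
#'
#' @return character vector of phrases (longest matched first).
#' @export
aut_stop_phrases <- function() {
  path <- system.file("extdata", "stop_phrases.txt", package = "blinkdt")
  if (nzchar(path)) {
    phrases <- readLines(path, warn = FALSE)
    phrases <- trimws(phrases)
    phrases <- phrases[nzchar(phrases) & !startsWith(phrases, "#")]
  } else {
    phrases <- c("used for", "use for", "used as", "use as",
                 "it can be", "can be", "you can", "to make",
                 "a", "an", "the", "to", "for", "as", "it")
  }
  phrases[order(-nchar(phrases))]
}

# crude but deterministic English singularisation; covers the regular
# plural forms that dominate one-word AUT responses
singularize_word <- function(w) {
  n <- nchar(w)
  if (n > 3 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 3 && (endsWith(w, "shes") || endsWith(w, "ches") ||
                endsWith(w, "xes") || endsWith(w, "zes") ||
                endsWith(w, "sses"))) {
    return(substr(w, 1, n - 2))
  }
  if (n > 2 && endsWith(w, "s") && !endsWith(w, "ss") &&
      !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1, n - 1))
  }
  w
}

#' Normalize a raw AUT response
#'
#' Lowercases, removes filler stop-phrases and articles, unifies singular
#' and plural word forms, and collapses whitespace, so that equivalent
#' responses map to the same string before frequency counting. The
#' operation is deterministic and idempotent.
#'
#' @param raw_text character vector of raw responses.
#' @param stop_phrases character vector of phrases to delete (whole-word
#'   matches); defaults to [aut_stop_phrases()].
#' @param singularize logical; apply the singular/plural unification rules.
#' @return character vector of normalized responses; entries that are
#'   empty after normalization are returned as `""` and should be treated
#'   as invalid (excluded from fluency).
#' @export
normalize_response <- function(raw_text,
                               stop_phrases = aut_stop_phrases(),
                               singularize = TRUE) {
  out <- tolower(trimws(as.character(raw_text)))
  for (ph in stop_phrases) {
    out <- gsub(paste0("\\b", ph, "\\b"), " ", out, fixed = FALSE)
  }
  out <- gsub("[[:space:]]+", " ", trimws(out))
  if (singularize) {
    out <- vapply(strsplit(out, " ", fixed = TRUE), function(ws)
      paste(vapply(ws, singularize_word, character(1)), collapse = " "),
      character(1))
  }
  out
}

# valid = non-empty normalized text
response_valid <- function(table) {
  !is.na(table$normalized_text) & nzchar(trimws(table$normalized_text))
}

#' Frequency-based (FB) originality: statistical infrequency
#'
#' For each object, a response's infrequency is 1 minus its relative
#' frequency among all responses given for that object across the whole
#' sample (a response given 8 times among 20 scores 1 - 8/20 = 0.60). The
#' per-participant score is the pooled mean infrequency over all of that
#' participant's valid responses.
#'
#' @param table long-format response data.frame with columns
#'   participant_id, object_id, normalized_text.
#' @return list with `per_response` (the input rows plus `infrequency`)
#'   and `per_participant` (participant_id, fb_originality).
#' @export
score_fb_originality <- function(table) {
  valid <- response_valid(table)
  if (any(!valid)) {
    warning(sum(!valid), " invalid (empty) responses excluded from ",
            "FB originality")
  }
  tab <- table[valid, , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid responses to score")
  key <- interaction(tab$object_id, tab$normalized_text, drop = TRUE)
  resp_count <- as.numeric(base::table(key)[key])
  obj_total <- as.numeric(
    base::table(tab$object_id)[as.character(tab$object_id)])
  tab$infrequency <- 1 - resp_count / obj_total
  per_part <- stats::aggregate(infrequency ~ participant_id, data = tab,
                               FUN = mean)
  names(per_part)[2] <- "fb_originality"
  list(per_response = tab, per_participant = per_part)
}

#' Flexibility and fluency
#'
#' Fluency is the count of valid responses over all objects. Flexibility
#' is the mean, over the objects present in the study table, of the number
#' of distinct conceptual categories the participant's responses for that
#' object draw from (0 for an object the participant did not attempt).
#'
#' @param table long-format response data.frame with columns
#'   participant_id, object_id, normalized_text, category_label.
#' @return data.frame (participant_id, fluency, flexibility). Participants
#'   whose responses are all invalid are excluded with a warning.
#' @export
score_flexibility_fluency <- function(table) {
  valid <- response_valid(table)
  all_parts <- unique(table$participant_id)
  tab <- table[valid, , drop = FALSE]
  objects <- unique(table$object_id)
  excluded <- setdiff(all_parts, unique(tab$participant_id))
  if (length(excluded) > 0) {
    warning("participants with zero valid responses excluded: ",
            paste(excluded, collapse = ", "))
  }
  res <- lapply(split(tab, tab$participant_id, drop = TRUE), function(d) {
    ncat <- vapply(objects, function(obj)
      length(unique(d$category_label[d$object_id == obj])), integer(1))
    data.frame(participant_id = d$participant_id[1],
               fluency = nrow(d),
               flexibility = mean(ncat))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rater-based (RB) originality
#'
#' Each idea's originality is the mean of the two judges' 1-5 ratings
#' (an optional `consensus_score` column, when non-missing, overrides the
#' mean, modelling the judges' consensus resolution of large
#' discrepancies); the participant score is the mean of idea scores across
#' the objects.
#'
#' @param table long-format response data.frame with columns
#'   participant_id, rater1_score, rater2_score and optionally
#'   consensus_score.
#' @return list with `per_idea` (input rows plus `idea_score`) and
#'   `per_participant` (participant_id, rb_originality). Ideas with a
#'   missing rating are excluded with a warning.
#' @export
score_rb_originality <- function(table) {
  ok <- response_valid(table) &
    !is.na(table$rater1_score) & !is.na(table$rater2_score)
  if (any(!ok)) {
    warning(sum(!ok), " ideas with missing ratings or invalid text ",
            "excluded from RB originality")
  }
  tab <- table[ok, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rated ideas to score")
  tab$idea_score <- (tab$rater1_score + tab$rater2_score) / 2
  if ("consensus_score" %in% names(tab)) {
    use <- !is.na(tab$consensus_score)
    tab$idea_score[use] <- tab$consensus_score[use]
  }
  per_part <- stats::aggregate(idea_score ~ participant_id, data = tab,
                               FUN = mean)
  names(per_part)[2] <- "rb_originality"
  list(per_idea = tab, per_participant = per_part)
}

#' Intraclass correlation ICC(2,k): two-way random, absolute agreement,
#' average measures
#'
#' Computed from the standard two-way mean squares: with MSB the
#' between-idea, MSJ the between-judge and MSE the residual mean square,
#' ICC(2,k) = (MSB - MSE) / (MSB + (MSJ - MSE)/n).
#'
#' @param rating_matrix numeric matrix, rows = ideas, columns = raters
#'   (>= 3 ideas, >= 2 raters).
#' @return an object of class `icc_result`: list(icc, variant, n_items,
#'   n_raters). When the between-idea variance is zero the ICC is
#'   undefined and reported as NA with a warning.
#' @export
compute_icc <- function(rating_matrix) {
  m <- as.matrix(rating_matrix)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3, k >= 2, !anyNA(m))
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssb <- k * sum((row_m - grand)^2)
  ssj <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssb - ssj
  msb <- ssb / (n - 1)
  msj <- ssj / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msb <= 0 || sst == 0) {
    warning("zero between-idea variance: ICC undefined")
    icc <- NA_real_
  } else {
    icc <- (msb - mse) / (msb + (msj - mse) / n)
  }
  structure(list(icc = icc,
                 variant = "ICC(2,k) two-way random, absolute agreement, average measures",
                 n_items = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f  [%s; %d items x %d raters]\n",
              x$icc, x$variant, x$n_items, x$n_raters))
  invisible(x)
}

#' Score a full AUT response table
#'
#' Convenience wrapper running normalization (when `normalized_text` is
#' absent), FB originality, flexibility/fluency and RB originality, and
#' merging them into one per-participant table.
#'
#' @param table long-format response data.frame.
#' @param ... passed to [normalize_response()].
#' @return list with `participants` (participant_id, fluency, flexibility,
#'   fb_originality, rb_originality), `icc` (an `icc_result` over all
#'   rated ideas), and `n_invalid` (count of excluded invalid responses).
#' @export
score_aut <- function(table, ...) {
  if (!"normalized_text" %in% names(table)) {
    table$normalized_text <- normalize_response(table$raw_text, ...)
  }
  n_invalid <- sum(!response_valid(table))
  fb <- suppressWarnings(score_fb_originality(table))
  ff <- suppressWarnings(score_flexibility_fluency(table))
  rb <- suppressWarnings(score_rb_originality(table))
  out <- merge(merge(ff, fb$per_participant, by = "participant_id"),
               rb$per_participant, by = "participant_id")
  icc <- compute_icc(as.matrix(
    rb$per_idea[, c("rater1_score", "rater2_score")]))
  list(participants = out, icc = icc, n_invalid = n_invalid)
}
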