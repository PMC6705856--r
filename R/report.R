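#' Build a cohort table of disc records
#'
#' One record per disc: subject, cohort label, level, Pfirrmann grade, HIZ
#' flag, optional exclusion flag + reason, and (optionally) metric columns.
#' (subject, level) pairs must be unique; excluded discs must carry a
#' reason and are omitted from all summaries.
#'
#' @param df data.frame with at least `subject`, `cohort`, `level`,
#'   `grade`, `hiz`; `excluded` / `reason` added when missing.
#' @return the validated data.frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  need <- c("subject", "cohort", "level", "grade", "hiz")
  stop_if_not(all(need %in% names(df)),
              paste("cohort table needs columns:", paste(need, collapse = ", ")))
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  if (!"reason" %in% names(df)) df$reason <- NA_character_
  stop_if_not(!anyDuplicated(df[, c("subject", "level")]),
              "(subject, level) must be unique")
  stop_if_not(all(df$grade %in% 1:5), "grades must be in 1..5")
  stop_if_not(all(!df$excluded | !is.na(df$reason)),
              "excluded discs must carry a reason")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Grade-by-HIZ summary of a cohort table
#'
#' For each cohort, counts of discs per Pfirrmann grade split into rows
#' "no_hiz", "hiz" and "all", plus a "1-5" total column, each with its
#' percentage of the cohort's included discs (rounded half-up to one
#' decimal, as such tables are conventionally printed).
#'
#' @param table a [cohort_table()] (or a plain data.frame accepted by it).
#' @return data.frame with columns `cohort`, `status`, `grade` (character
#'   "1".."5" or "1-5"), `n`, `pct`.
#' @export
summarize_cohort <- function(table) {
  tab <- cohort_table(as.data.frame(table))
  tab <- tab[!tab$excluded, , drop = FALSE]
  stop_if_not(nrow(tab) > 0, "no included discs to summarise")
  out <- list()
  for (co in unique(tab$cohort)) {
    sub <- tab[tab$cohort == co, ]
    total <- nrow(sub)
    for (status in c("no_hiz", "hiz", "all")) {
      sel <- switch(status,
                    no_hiz = sub[!sub$hiz, ],
                    hiz = sub[sub$hiz, ],
                    all = sub)
      ns <- vapply(1:5, function(g) sum(sel$grade == g), numeric(1))
      ns <- c(ns, sum(ns))
      out[[length(out) + 1]] <- data.frame(
        cohort = co, status = status, grade = c(as.character(1:5), "1-5"),
        n = ns, pct = round_half_up(100 * ns / total, 1),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subject-level HIZ prevalence per cohort
#'
#' Fraction of subjects having at least one disc with an HIZ.
#'
#' @param table a [cohort_table()].
#' @return data.frame with `cohort`, `n_subjects`, `n_with_hiz`,
#'   `prevalence` (fraction) and `prevalence_pct` (half-up, 1 decimal).
#' @export
hiz_prevalence <- function(table) {
  tab <- cohort_table(as.data.frame(table))
  tab <- tab[!tab$excluded, , drop = FALSE]
  out <- list()
  for (co in unique(tab$cohort)) {
    sub <- tab[tab$cohort == co, ]
    subj <- unique(sub$subject)
    with_hiz <- unique(sub$subject[sub$hiz])
    frac <- length(with_hiz) / length(subj)
    out[[length(out) + 1]] <- data.frame(
      cohort = co, n_subjects = length(subj), n_with_hiz = length(with_hiz),
      prevalence = frac, prevalence_pct = round_half_up(100 * frac, 1),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference grade-by-HIZ cohort counts
#'
#' A published lumbar cohort's distribution of intervertebral discs over
#' Pfirrmann grades and HIZ status (25 low-back-pain patients, 124 discs;
#' 12 controls, 59 discs), shipped as a plain-text fixture.  Used as the
#' package's worked example for [summarize_cohort()] arithmetic.
#'
#' @return data.frame with columns `cohort`, `grade`, `hiz`, `n`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.csv",
                      package = "ivdquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expand per-stratum counts into a disc-level cohort table
#'
#' Turns a counts table (cohort, grade, hiz, n) into one synthetic record
#' per disc, assigning subject identifiers so that a chosen number of
#' subjects per cohort carry the HIZ discs (for prevalence arithmetic).
#'
#' @param counts data.frame with `cohort`, `grade`, `hiz`, `n`.
#' @param n_subjects named list/vector: subjects per cohort.
#' @param n_subjects_with_hiz named list/vector: how many distinct subjects
#'   per cohort carry the HIZ discs.
#' @return a [cohort_table()].
#' @export
expand_counts <- function(counts, n_subjects, n_subjects_with_hiz) {
  rows <- list()
  for (co in unique(counts$cohort)) {
    sub <- counts[counts$cohort == co, ]
    ns <- n_subjects[[co]]
    nh <- n_subjects_with_hiz[[co]]
    grades <- rep(sub$grade, sub$n)
    hiz <- rep(sub$hiz, sub$n)
    n_discs <- length(grades)
    # HIZ discs spread over the first nh subjects, the rest round-robin
    subj <- integer(n_discs)
    hidx <- which(hiz)
    subj[hidx] <- ((seq_along(hidx) - 1) %% nh) + 1
    oidx <- which(!hiz)
    subj[oidx] <- ((seq_along(oidx) - 1) %% ns) + 1
    rows[[length(rows) + 1]] <- data.frame(
      subject = sprintf("%s%02d", co, subj), cohort = co,
      level = sprintf("D%03d", seq_len(n_discs)),
      grade = grades, hiz = hiz, stringsAsFactors = FALSE)
  }
  cohort_table(do.call(rbind, rows))
}
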