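#' Evidence lines recognised by the triangulation
#' @export
evidence_lines <- c("archaeobotany", "historical", "linguistic")

evidence_attr_cols <- c("find_present", "context_confirmed_use",
                        "n_unrelated_sources", "name_attested",
                        "use_indicating_name", "traceable_to_old_norse",
                        "pre_viking_loan_phonology", "override_score")

#' Build an evidence table
#'
#' One row per plant x use x evidence line, with typed attribute columns.
#' Missing attribute columns are filled with their "no evidence" value.
#' Logical implications among attributes are enforced: a use confirmed by
#' archaeological context implies a find; a pre-Viking loan phonology
#' implies traceability to Old Norse; traceability implies an attested
#' name.
#'
#' @param df data frame with at least \code{plant}, \code{use},
#'   \code{line}; recognised attributes: \code{find_present},
#'   \code{context_confirmed_use} (archaeobotany),
#'   \code{n_unrelated_sources} (historical), \code{name_attested},
#'   \code{use_indicating_name}, \code{traceable_to_old_norse},
#'   \code{pre_viking_loan_phonology} (linguistic), and an optional
#'   \code{override_score} (1-5) recording expert judgment that departs
#'   from the mechanical rubric.
#' @return validated data frame of class \code{evidence_table}.
#' @export
evidence_table <- function(df) {
  need <- c("plant", "use", "line")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  bad <- setdiff(unique(df$line), evidence_lines)
  if (length(bad))
    stop("unknown evidence line(s): ", paste(bad, collapse = ", "))
  for (col in evidence_attr_cols) {
    if (!col %in% names(df)) {
      fill <- if (col == "n_unrelated_sources") 0L
              else if (col == "override_score") NA_integer_
              else FALSE
      df[[col]] <- rep(fill, nrow(df))
    }
  }
  flags <- setdiff(evidence_attr_cols,
                   c("n_unrelated_sources", "override_score"))
  for (col in flags) {
    df[[col]] <- !is.na(df[[col]]) & as.logical(df[[col]])
  }
  df$n_unrelated_sources[is.na(df$n_unrelated_sources)] <- 0L
  if (any(df$n_unrelated_sources < 0)) stop("source counts must be >= 0")
  ov <- df$override_score
  if (any(!is.na(ov) & !(ov %in% 1:5)))
    stop("override_score must be in 1..5")
  # implications
  df$find_present <- df$find_present | df$context_confirmed_use
  df$traceable_to_old_norse <- df$traceable_to_old_norse |
    df$pre_viking_loan_phonology
  df$name_attested <- df$name_attested | df$traceable_to_old_norse |
    df$use_indicating_name
  class(df) <- c("evidence_table", "data.frame")
  df
}

#' Read an evidence table from CSV
#' @param path CSV file with \code{\link{evidence_table}} columns.
#' @export
read_evidence <- function(path) {
  evidence_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Score one evidence line on the 1-5 Likert scale
#'
#' Deterministic rubric (1 = no evidence, 2 = unlikely / indirect only,
#' 3 = possible but not confirmed, 4 = highly likely, 5 = confirmed):
#' \itemize{
#'   \item archaeobotany: a find whose archaeological context confirms the
#'     use scores 5; a find without use context 3; no find 1.
#'   \item historical: mentions of the use in two or more unrelated
#'     sources score 4; a single source 3; none 1.
#'   \item linguistic: a name whose loan phonology predates the Viking Age
#'     scores 5; a use-indicating name traceable to Old Norse 4; a
#'     use-indicating name alone 3; an attested name with no use signal 2;
#'     nothing 1.
#' }
#' A non-missing \code{override_score} replaces the rubric value.
#'
#' @param record a one-row data frame (or list) with \code{line} and the
#'   relevant attributes.
#' @return integer score in 1..5.
#' @export
score_line <- function(record) {
  record <- evidence_table(as.data.frame(record, stringsAsFactors = FALSE))
  owner <- list(
    archaeobotany = c("find_present", "context_confirmed_use"),
    historical = "n_unrelated_sources",
    linguistic = c("name_attested", "use_indicating_name",
                   "traceable_to_old_norse", "pre_viking_loan_phonology"))
  for (i in seq_len(nrow(record))) {
    foreign <- setdiff(unlist(owner[setdiff(names(owner),
                                            record$line[i])]),
                       owner[[record$line[i]]])
    set <- vapply(foreign, function(col) {
      v <- record[[col]][i]
      if (is.logical(v)) isTRUE(v) else !is.na(v) && v > 0
    }, TRUE)
    if (any(set))
      stop("attributes not valid for line '", record$line[i], "': ",
           paste(foreign[set], collapse = ", "))
  }
  score_lines(record)
}

# vectorized rubric over a validated evidence_table
score_lines <- function(df) {
  s <- integer(nrow(df))
  a <- df$line == "archaeobotany"
  s[a] <- ifelse(df$context_confirmed_use[a], 5L,
                 ifelse(df$find_present[a], 3L, 1L))
  h <- df$line == "historical"
  s[h] <- ifelse(df$n_unrelated_sources[h] >= 2, 4L,
                 ifelse(df$n_unrelated_sources[h] == 1, 3L, 1L))
  l <- df$line == "linguistic"
  s[l] <- ifelse(df$pre_viking_loan_phonology[l], 5L,
          ifelse(df$traceable_to_old_norse[l] & df$use_indicating_name[l],
                 4L,
          ifelse(df$use_indicating_name[l], 3L,
          ifelse(df$name_attested[l], 2L, 1L))))
  ov <- df$override_score
  s[!is.na(ov)] <- as.integer(ov[!is.na(ov)])
  s
}

#' Triangulate evidence into per-plant-use Likert verdicts
#'
#' Scores every evidence record, then combines lines per (plant, use) by
#' taking the maximum line score (an absent line contributes 1): a single
#' confirmed line suffices for a confirmed verdict. A combined score of 4
#' or 5 is interpreted as evidence of Viking-Age use.
#'
#' @param evidence an \code{evidence_table} (or coercible data frame).
#' @param positive_min combined score counted as positive (default 4).
#' @return data frame of class \code{likert_scores}: one row per
#'   (plant, use) with per-line scores, \code{combined},
#'   \code{positive} and a \code{rationale} string.
#' @export
triangulate <- function(evidence, positive_min = 4) {
  ev <- evidence_table(evidence)
  if (nrow(ev) == 0L) {
    out <- data.frame(plant = character(), use = character(),
                      archaeobotany = integer(), historical = integer(),
                      linguistic = integer(), combined = integer(),
                      positive = logical(), rationale = character())
    class(out) <- c("likert_scores", "data.frame")
    return(out)
  }
  ev$score <- score_lines(ev)
  key <- paste(ev$plant, ev$use, sep = "|")
  dup <- duplicated(ev[c("plant", "use", "line")])
  if (any(dup)) {
    # identical duplicates collapse; conflicting ones are an error
    chk <- tapply(ev$score, paste(key, ev$line), function(x)
      length(unique(x)) > 1)
    if (any(chk))
      stop("conflicting duplicate evidence records for: ",
           paste(names(chk)[chk], collapse = ", "))
    ev <- ev[!dup, ]
    key <- paste(ev$plant, ev$use, sep = "|")
  }
  keys <- unique(key)
  out <- data.frame(plant = ev$plant[match(keys, key)],
                    use = ev$use[match(keys, key)],
                    archaeobotany = 1L, historical = 1L, linguistic = 1L,
                    stringsAsFactors = FALSE)
  for (ln in evidence_lines) {
    rows <- ev$line == ln
    out[[ln]][match(key[rows], keys)] <- ev$score[rows]
  }
  # carry use-level metadata when present
  for (extra in c("level", "general_category")) {
    if (extra %in% names(ev))
      out[[extra]] <- ev[[extra]][match(keys, key)]
  }
  out$combined <- pmax(out$archaeobotany, out$historical, out$linguistic)
  out$positive <- out$combined >= positive_min
  out$rationale <- sprintf(
    "archaeobotany=%d; historical=%d; linguistic=%d; combined=max=%d (%s)",
    out$archaeobotany, out$historical, out$linguistic, out$combined,
    ifelse(out$positive, "positive", "not positive"))
  rownames(out) <- NULL
  class(out) <- c("likert_scores", "data.frame")
  out
}
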