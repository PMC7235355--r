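#' Define the item-level scale metadata for a study
#'
#' Builds the per-item metadata table that drives validation, reverse coding
#' and community assignment throughout the pipeline. Each item belongs to
#' exactly one instrument and one community (the predefined symptom cluster
#' used for bridge analysis, e.g. eating-disorder items vs autism-trait
#' items).
#'
#' @param item_id character vector of unique item identifiers.
#' @param instrument character vector (recycled) naming the questionnaire.
#' @param community character vector (recycled) of community labels.
#' @param likert_min,likert_max integer response bounds per item (recycled).
#' @param reverse_coded logical (recycled); `TRUE` for items whose scale
#'   direction must be flipped so that higher always means more symptoms.
#' @return A data.frame of class `scale_definition`, one row per item.
#' @examples
#' scale_definitions(c("ED01", "ED02"), "eating-disorder-scale", "ED", 0, 6)
#' @export
scale_definitions <- function(item_id, instrument, community,
                              likert_min, likert_max, reverse_coded = FALSE) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id))
    stop("item_id values must be unique within a study")
  out <- data.frame(
    item_id = item_id,
    instrument = rep_len(as.character(instrument), length(item_id)),
    community = rep_len(as.character(community), length(item_id)),
    likert_min = rep_len(as.integer(likert_min), length(item_id)),
    likert_max = rep_len(as.integer(likert_max), length(item_id)),
    reverse_coded = rep_len(as.logical(reverse_coded), length(item_id)),
    stringsAsFactors = FALSE
  )
  if (any(out$likert_min >= out$likert_max))
    stop("likert_min must be strictly less than likert_max for every item")
  class(out) <- c("scale_definition", "data.frame")
  out
}

#' Read scale metadata from a YAML or JSON file
#'
#' The file holds a list of records with fields `item_id`, `instrument`,
#' `community`, `likert_min`, `likert_max` and optionally `reverse_coded`
#' (default `FALSE`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `scale_definition` data.frame.
#' @export
read_scale_metadata <- function(path) {
  if (!file.exists(path)) stop("scale metadata file not found: ", path)
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (length(recs) == 0L) stop("scale metadata file is empty: ", path)
  get_field <- function(r, f, default = NULL) {
    v <- r[[f]]
    if (is.null(v)) {
      if (is.null(default)) stop("scale metadata record missing field '", f, "'")
      v <- default
    }
    v
  }
  scale_definitions(
    item_id = vapply(recs, get_field, "", f = "item_id"),
    instrument = vapply(recs, get_field, "", f = "instrument"),
    community = vapply(recs, get_field, "", f = "community"),
    likert_min = vapply(recs, function(r) as.integer(get_field(r, "likert_min")), 1L),
    likert_max = vapply(recs, function(r) as.integer(get_field(r, "likert_max")), 1L),
    reverse_coded = vapply(recs, function(r) isTRUE(get_field(r, "reverse_coded", FALSE)), TRUE)
  )
}

#' Write scale metadata to YAML
#'
#' @param scales a `scale_definition` data.frame.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_scale_metadata <- function(scales, path) {
  recs <- lapply(seq_len(nrow(scales)), function(i) {
    list(item_id = scales$item_id[i],
         instrument = scales$instrument[i],
         community = scales$community[i],
         likert_min = scales$likert_min[i],
         likert_max = scales$likert_max[i],
         reverse_coded = scales$reverse_coded[i])
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

new_item_response_matrix <- function(values, respondent_ids, scales) {
  storage.mode(values) <- "integer"
  dimnames(values) <- list(respondent_ids, scales$item_id)
  structure(
    list(values = values,
         respondent_ids = respondent_ids,
         scales = scales,
         n = nrow(values),
         p = ncol(values),
         missing_fraction = mean(is.na(values))),
    class = "item_response_matrix"
  )
}

#' @export
print.item_response_matrix <- function(x, ...) {
  cat(sprintf("Item response matrix: %d respondents x %d items (%s)\n",
              x$n, x$p,
              paste(sprintf("%s: %d", names(table(x$scales$community)),
                            as.integer(table(x$scales$community))),
                    collapse = ", ")))
  cat(sprintf("Missing cells: %d (%.2f%% of all responses)\n",
              sum(is.na(x$values)), 100 * x$missing_fraction))
  invisible(x)
}

#' Load item-level questionnaire responses from a wide CSV
#'
#' Reads a respondents x items table whose header row must match the
#' `item_id`s in `scales`, validates every response against the item's
#' declared Likert range, and (by default) applies reverse coding from the
#' metadata. Respondents with a few missing answers are retained; the
#' missing fraction is recorded on the returned object.
#'
#' @param path CSV path. An optional first column named `respondent_id` (or
#'   any column not matching an item) is used as respondent identifier when
#'   `id_column` names it.
#' @param scales a `scale_definition` data.frame covering every item column.
#' @param missing_tokens strings treated as missing (besides empty cells).
#' @param id_column optional name of a respondent-identifier column.
#' @param apply_reverse_coding apply [reverse_code()] before returning
#'   (recommended: reverse coding comes from metadata, never from data).
#' @return An `item_response_matrix`.
#' @export
load_responses <- function(path, scales, missing_tokens = c("", "NA"),
                           id_column = NULL, apply_reverse_coding = TRUE) {
  if (!file.exists(path)) stop("response file not found: ", path)
  raw <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "character",
             na.strings = missing_tokens),
    error = function(e) stop("failed to parse response CSV: ", conditionMessage(e))
  )
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    stop("response file has no data rows: ", path)
  respondent_ids <- if (!is.null(id_column) && id_column %in% names(raw)) {
    ids <- raw[[id_column]]
    raw <- raw[setdiff(names(raw), id_column)]
    ids
  } else {
    sprintf("R%03d", seq_len(nrow(raw)))
  }
  unknown <- setdiff(names(raw), scales$item_id)
  if (length(unknown) > 0L)
    stop("unknown item column(s) not in scale metadata: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(scales$item_id, names(raw))
  if (length(absent) > 0L)
    stop("item(s) declared in metadata but absent from CSV: ",
         paste(absent, collapse = ", "))
  raw <- raw[scales$item_id]
  values <- matrix(NA_integer_, nrow(raw), ncol(raw))
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    ok <- is.na(col) | grepl("^\\s*-?[0-9]+\\s*$", col)
    if (!all(ok))
      stop(sprintf("non-integer value '%s' at row %d, item %s",
                   col[which(!ok)[1]], which(!ok)[1], scales$item_id[j]))
    v <- as.integer(col)
    bad <- which(!is.na(v) & (v < scales$likert_min[j] | v > scales$likert_max[j]))
    if (length(bad) > 0L)
      stop(sprintf(
        "value %d out of declared range [%d, %d] at row %d, item %s",
        v[bad[1]], scales$likert_min[j], scales$likert_max[j],
        bad[1], scales$item_id[j]))
    values[, j] <- v
  }
  m <- new_item_response_matrix(values, respondent_ids, scales)
  if (apply_reverse_coding) m <- reverse_code(m) else m
}

#' Reverse-code flagged items
#'
#' For every item with `reverse_coded = TRUE`, maps each response `v` to
#' `likert_min + likert_max - v` so that higher values always indicate more
#' symptoms. Missing values stay missing. The flag is consumed: returned
#' metadata has `reverse_coded = FALSE` everywhere, so applying the
#' function again is the identity.
#'
#' @param m an `item_response_matrix`.
#' @return The recoded `item_response_matrix`.
#' @export
reverse_code <- function(m) {
  stopifnot(inherits(m, "item_response_matrix"))
  flags <- m$scales$reverse_coded
  values <- m$values
  for (j in which(flags)) {
    values[, j] <- m$scales$likert_min[j] + m$scales$likert_max[j] - values[, j]
  }
  scales <- m$scales
  scales$reverse_coded <- FALSE
  out <- new_item_response_matrix(values, m$respondent_ids, scales)
  attr(out, "reversed_items") <- m$scales$item_id[flags]
  out
}

#' Item-by-item correlation matrix
#'
#' Computes the correlation matrix that feeds redundancy screening and the
#' graphical lasso. Spearman is the default: responses are ordinal and a
#' rank correlation is invariant to the (unknown) monotone link between the
#' latent trait and the response categories. Missing cells are handled
#' pairwise-complete by default, mirroring the retention of respondents
#' with a handful of missing answers. If pairwise deletion leaves the
#' matrix indefinite it is projected to the nearest correlation matrix by
#' eigenvalue clipping (with a warning).
#'
#' @param m an `item_response_matrix`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param missing_policy `"pairwise"` (default) or `"complete"` cases.
#' @return A `correlation_matrix` object: list with `S` (p x p matrix),
#'   `n_effective` (per-pair complete counts), `method`, and `n` (number of
#'   respondents, used downstream as the likelihood sample size).
#' @export
correlation_matrix <- function(m, method = c("spearman", "pearson"),
                               missing_policy = c("pairwise", "complete")) {
  stopifnot(inherits(m, "item_response_matrix"))
  method <- match.arg(method)
  missing_policy <- match.arg(missing_policy)
  x <- m$values
  storage.mode(x) <- "double"
  if (missing_policy == "complete") x <- x[stats::complete.cases(x), , drop = FALSE]
  vars <- apply(x, 2, function(col) var(col, na.rm = TRUE))
  if (any(!is.finite(vars) | vars == 0))
    stop("zero-variance item(s): ",
         paste(m$scales$item_id[!is.finite(vars) | vars == 0], collapse = ", "))
  present <- !is.na(x)
  n_eff <- crossprod(present)
  if (any(n_eff < 3L))
    stop("fewer than 3 pairwise-complete observations for some item pair")
  S <- fast_cor(x, method)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warning("pairwise-complete correlation matrix is indefinite; ",
            "projecting to the nearest positive semidefinite matrix")
    vals <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  }
  dimnames(S) <- list(m$scales$item_id, m$scales$item_id)
  structure(
    list(S = S, n_effective = n_eff, method = method, n = nrow(x),
         items = m$scales$item_id, communities = m$scales$community),
    class = "correlation_matrix"
  )
}

#' Write a correlation matrix as CSV with item ids on both margins
#'
#' @param cm a `correlation_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(cm, path) {
  df <- data.frame(item_id = rownames(cm$S), cm$S, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an item response matrix as the wide CSV that [load_responses()] reads
#'
#' @param m an `item_response_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses_csv <- function(m, path) {
  df <- data.frame(respondent_id = m$respondent_ids, m$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Pairwise-complete correlations with a fast path for Spearman: on complete
# data (or complete column pairs) rank-transforming once and taking Pearson
# correlations is exactly pairwise Spearman, and avoids base cor()'s
# per-pair re-ranking. Pairs involving columns with missing cells are
# recomputed exactly (re-ranked within the pairwise-complete subset).
fast_cor <- function(x, method) {
  if (method == "pearson") return(cor(x, use = "pairwise.complete.obs"))
  rx <- apply(x, 2, rank, na.last = "keep")
  S <- cor(rx, use = "pairwise.complete.obs")
  na_cols <- which(colSums(is.na(x)) > 0)
  for (j in na_cols) {
    S[j, ] <- S[, j] <- suppressWarnings(
      cor(x[, j], x, use = "pairwise.complete.obs", method = "spearman"))
    S[j, j] <- 1
  }
  S
}

# Drop items by id, keeping metadata in sync; internal helper shared by the
# redundancy module and the bootstrap machinery.
drop_items <- function(m, item_ids) {
  keep <- !(m$scales$item_id %in% item_ids)
  scales <- m$scales[keep, , drop = FALSE]
  rownames(scales) <- NULL
  new_item_response_matrix(m$values[, keep, drop = FALSE], m$respondent_ids, scales)
}

# Subset respondents by row index; used by the resampling module.
subset_respondents <- function(m, idx) {
  new_item_response_matrix(m$values[idx, , drop = FALSE],
                           m$respondent_ids[idx], m$scales)
}
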