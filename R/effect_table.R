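#' Sparse multi-factor effect table
#'
#' An `effect_table` holds study-level log odds ratios and their within-study
#' standard errors for several risk factors at once, where each study reports
#' only a subset of factors. It is the single currency of the package: the
#' frequentist pooling functions, the Bayesian multivariate models and the
#' synthetic-data generator all consume and produce this structure.
#'
#' @param log_or numeric matrix (studies x factors) of log odds ratios;
#'   `NA` marks a factor the study does not report. A stored `0` is an
#'   observed estimate, never a stand-in for missing.
#' @param se numeric matrix of the same dimension with within-study standard
#'   errors; must be strictly positive wherever `log_or` is observed and `NA`
#'   exactly where `log_or` is `NA`.
#' @param studies optional data frame with columns `study_id` and
#'   `citation_label`; defaults are derived from the row names of `log_or`.
#' @param factors optional data frame with columns `factor_id`,
#'   `display_name`, `contrast` and `higher_is_risk`; defaults are derived
#'   from the column names of `log_or`.
#'
#' @return An object of class `effect_table` with components `log_or`, `se`,
#'   `studies` and `factors`. The missingness mask is implied by `is.na()`.
#' @seealso [read_effect_table()], [glottic_table1()], [filter_min_studies()]
#' @export
#' @examples
#' y <- matrix(c(0.5, NA, 0.2, 0.4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("aci", "age")))
#' s <- matrix(c(0.2, NA, 0.1, 0.3), 2, 2, dimnames = dimnames(y))
#' effect_table(y, s)
effect_table <- function(log_or, se, studies = NULL, factors = NULL) {
  log_or <- as.matrix(log_or)
  se <- as.matrix(se)
  if (is.null(rownames(log_or)))
    rownames(log_or) <- paste0("study_", seq_len(nrow(log_or)))
  if (is.null(colnames(log_or)))
    colnames(log_or) <- paste0("factor_", seq_len(ncol(log_or)))
  dimnames(se) <- dimnames(log_or)
  if (is.null(studies)) {
    studies <- data.frame(study_id = rownames(log_or),
                          citation_label = rownames(log_or),
                          stringsAsFactors = FALSE)
  }
  if (is.null(factors)) {
    factors <- data.frame(factor_id = colnames(log_or),
                          display_name = colnames(log_or),
                          contrast = "unspecified",
                          higher_is_risk = TRUE,
                          stringsAsFactors = FALSE)
  }
  x <- structure(list(log_or = log_or, se = se,
                      studies = studies, factors = factors),
                 class = "effect_table")
  validate_effect_table(x)
  x
}

#' Validate an effect table
#'
#' Checks every structural invariant: matching dimensions, unique study and
#' factor identifiers, at least one estimate per study, a consistent
#' missingness mask between the estimate and standard-error layers, finite
#' log ORs and strictly positive SEs. Called by every constructor; exported
#' so that externally assembled objects can be checked too.
#'
#' @param x an `effect_table`.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   cell or identifier.
#' @export
validate_effect_table <- function(x) {
  stopifnot(inherits(x, "effect_table"))
  y <- x$log_or; s <- x$se
  if (!identical(dim(y), dim(s)))
    stop("log_or and se matrices must have identical dimensions")
  if (anyDuplicated(rownames(y)))
    stop("duplicate study_id: ", rownames(y)[duplicated(rownames(y))][1])
  if (anyDuplicated(colnames(y)))
    stop("duplicate factor_id: ", colnames(y)[duplicated(colnames(y))][1])
  if (!identical(x$studies$study_id, rownames(y)))
    stop("studies table out of step with matrix row names")
  if (!identical(x$factors$factor_id, colnames(y)))
    stop("factors table out of step with matrix column names")
  if (any(nchar(x$factors$contrast) == 0))
    stop("every factor needs a non-empty contrast description")
  bad_mask <- is.na(y) != is.na(s)
  if (any(bad_mask)) {
    idx <- which(bad_mask, arr.ind = TRUE)[1, ]
    stop(sprintf("estimate/SE missingness mismatch at (%s, %s)",
                 rownames(y)[idx[1]], colnames(y)[idx[2]]))
  }
  if (any(!is.finite(y[!is.na(y)])))
    stop("non-finite log odds ratio present")
  bad_se <- !is.na(s) & s <= 0
  if (any(bad_se)) {
    idx <- which(bad_se, arr.ind = TRUE)[1, ]
    stop(sprintf("standard error must be > 0 at (%s, %s)",
                 rownames(y)[idx[1]], colnames(y)[idx[2]]))
  }
  if (any(rowSums(!is.na(y)) == 0))
    stop("study with no estimates: ",
         rownames(y)[which(rowSums(!is.na(y)) == 0)[1]])
  invisible(x)
}

#' @export
print.effect_table <- function(x, ...) {
  m <- !is.na(x$log_or)
  cat(sprintf("effect_table: %d studies x %d factors (%d of %d cells observed, %.0f%% sparse)\n",
              nrow(m), ncol(m), sum(m), length(m), 100 * (1 - mean(m))))
  cnt <- reporting_counts(x)
  cat("factors:", paste(sprintf("%s[%d]", names(cnt), cnt), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.effect_table <- function(x, ...) {
  obs <- which(!is.na(x$log_or), arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  data.frame(study = rownames(x$log_or)[obs[, 1]],
             factor = colnames(x$log_or)[obs[, 2]],
             log_or = x$log_or[obs],
             se = x$se[obs],
             stringsAsFactors = FALSE)
}

#' Number of reporting studies per factor
#'
#' @param table an `effect_table`.
#' @return Named integer vector: for each factor, how many studies report it.
#' @export
#' @examples
#' reporting_counts(glottic_table1())
reporting_counts <- function(table) {
  stopifnot(inherits(table, "effect_table"))
  colSums(!is.na(table$log_or))
}

#' Keep factors reported by at least k studies
#'
#' Applies the inclusion rule used to decide which factors enter the
#' multivariate model: a factor is retained only when at least `k` studies
#' report it. Studies left with no estimates afterwards are dropped. The
#' original study and factor ordering is preserved, so the operation is
#' idempotent.
#'
#' @param table an `effect_table`.
#' @param k minimum number of reporting studies (integer, >= 1).
#' @return A filtered `effect_table`.
#' @export
#' @examples
#' filter_min_studies(glottic_table1(), 2)
filter_min_studies <- function(table, k) {
  stopifnot(inherits(table, "effect_table"))
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a single integer >= 1")
  keep <- reporting_counts(table) >= k
  if (!any(keep)) stop("no factor reported by >= ", k, " studies")
  select_factors(table, names(keep)[keep])
}

#' Subset an effect table by factor
#'
#' @param table an `effect_table`.
#' @param factor_ids character vector of factor identifiers to keep, in their
#'   original table order.
#' @return An `effect_table` restricted to those factors; studies left with
#'   no estimates are dropped.
#' @export
select_factors <- function(table, factor_ids) {
  stopifnot(inherits(table, "effect_table"))
  miss <- setdiff(factor_ids, colnames(table$log_or))
  if (length(miss)) stop("unknown factor: ", paste(miss, collapse = ", "))
  jj <- colnames(table$log_or) %in% factor_ids
  y <- table$log_or[, jj, drop = FALSE]
  s <- table$se[, jj, drop = FALSE]
  ii <- rowSums(!is.na(y)) > 0
  effect_table(y[ii, , drop = FALSE], s[ii, , drop = FALSE],
               studies = table$studies[ii, , drop = FALSE],
               factors = table$factors[jj, , drop = FALSE])
}

#' Blank a single cell of an effect table
#'
#' Marks one (study, factor) estimate as unreported. Used to run alternative
#' inclusion variants when the exact fitted dataset is ambiguous (e.g.
#' leave-one-out bracketing of a factor's study count). If blanking the cell
#' empties the study's row, the study is dropped.
#'
#' @param table an `effect_table`.
#' @param study_id,factor_id identifiers of the cell to blank.
#' @return The modified `effect_table`.
#' @export
drop_cell <- function(table, study_id, factor_id) {
  stopifnot(inherits(table, "effect_table"))
  if (!study_id %in% rownames(table$log_or)) stop("unknown study: ", study_id)
  if (!factor_id %in% colnames(table$log_or)) stop("unknown factor: ", factor_id)
  if (is.na(table$log_or[study_id, factor_id]))
    stop(sprintf("cell (%s, %s) is already missing", study_id, factor_id))
  y <- table$log_or; s <- table$se
  y[study_id, factor_id] <- NA_real_
  s[study_id, factor_id] <- NA_real_
  ii <- rowSums(!is.na(y)) > 0
  effect_table(y[ii, , drop = FALSE], s[ii, , drop = FALSE],
               studies = table$studies[ii, , drop = FALSE],
               factors = table$factors)
}

re_cell <- "^\\s*(-?[0-9]*\\.?[0-9]+)\\s*\\(\\s*(-?[0-9]*\\.?[0-9]+)\\s*\\)\\s*$"

#' Read an effect table from CSV
#'
#' Two layouts are supported. `long`: columns `study`, `factor`, `log_or`,
#' `se`, one row per observed cell. `wide`: one row per study, first column
#' the study identifier, remaining columns one per factor with cells of the
#' form `"0.51 (0.16)"`; blank cells mean the study does not report the
#' factor. Blanks always become missing entries, never zeros.
#'
#' @param path path to a CSV file (UTF-8, dot decimal separator).
#' @param layout `"long"` (default) or `"wide"`.
#' @return A validated `effect_table`. Factor order follows first appearance
#'   (long) or column order (wide); study order follows first appearance.
#' @export
read_effect_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "long") {
    need <- c("study", "factor", "log_or", "se")
    if (!all(need %in% names(d)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    dup <- duplicated(d[, c("study", "factor")])
    if (any(dup))
      stop(sprintf("duplicate (study, factor) pair: (%s, %s)",
                   d$study[dup][1], d$factor[dup][1]))
    for (col in c("log_or", "se")) {
      v <- suppressWarnings(as.numeric(d[[col]]))
      if (any(is.na(v)))
        stop(sprintf("non-numeric %s at (%s, %s)", col,
                     d$study[is.na(v)][1], d$factor[is.na(v)][1]))
      d[[col]] <- v
    }
    bad <- d$se <= 0
    if (any(bad))
      stop(sprintf("standard error must be > 0 at (%s, %s)",
                   d$study[bad][1], d$factor[bad][1]))
    studies <- unique(d$study)
    factors <- unique(d$factor)
    y <- s <- matrix(NA_real_, length(studies), length(factors),
                     dimnames = list(studies, factors))
    y[cbind(d$study, d$factor)] <- d$log_or
    s[cbind(d$study, d$factor)] <- d$se
    return(effect_table(y, s))
  }
  # wide layout
  studies <- as.character(d[[1]])
  vals <- d[, -1, drop = FALSE]
  factors <- names(vals)
  y <- s <- matrix(NA_real_, length(studies), length(factors),
                   dimnames = list(studies, factors))
  for (j in seq_along(factors)) {
    cell <- as.character(vals[[j]])
    filled <- !is.na(cell) & trimws(cell) != ""
    for (i in which(filled)) {
      m <- regmatches(cell[i], regexec(re_cell, cell[i]))[[1]]
      if (length(m) != 3)
        stop(sprintf("cannot parse cell '%s' at (%s, %s); expected 'value (se)'",
                     cell[i], studies[i], factors[j]))
      y[i, j] <- as.numeric(m[2])
      s[i, j] <- as.numeric(m[3])
      if (s[i, j] <= 0)
        stop(sprintf("standard error must be > 0 at (%s, %s)",
                     studies[i], factors[j]))
    }
  }
  effect_table(y, s)
}

#' Write an effect table to CSV
#'
#' Inverse of [read_effect_table()]: round-trips cell-for-cell including the
#' missingness pattern in either layout.
#'
#' @param table an `effect_table`.
#' @param path output file path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(table, path, layout = c("long", "wide")) {
  stopifnot(inherits(table, "effect_table"))
  layout <- match.arg(layout)
  if (layout == "long") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  } else {
    y <- table$log_or; s <- table$se
    cells <- matrix("", nrow(y), ncol(y), dimnames = dimnames(y))
    obs <- !is.na(y)
    cells[obs] <- sprintf("%.10g (%.10g)", y[obs], s[obs])
    d <- data.frame(study = rownames(y), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
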