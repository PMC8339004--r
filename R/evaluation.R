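#' Matched-ratings container
#'
#' The bridge between mark lists and FROC/wAFROC analysis: per-lesion
#' ratings (the score of the matched mark, `-Inf` when unmarked), all
#' non-lesion (false-positive) mark scores, and the case roster. Built by
#' [match_marks()] or [ratings_from_table()].
#'
#' @param lesion_ratings tibble with `case_id`, `lesion_id`, `weight`,
#'   `rating` (`-Inf` = unmarked).
#' @param nl tibble with `case_id`, `score`: every non-lesion mark.
#' @param cases tibble with `case_id`, `n_lesions` covering all cases,
#'   including nodule-free ones.
#' @return object of class `matched_ratings`.
#' @export
matched_ratings <- function(lesion_ratings, nl, cases) {
  cases <- as_tibble(cases)
  lesion_ratings <- as_tibble(lesion_ratings)
  nl <- as_tibble(nl)
  if (nrow(lesion_ratings)) {
    ws <- tapply(lesion_ratings$weight, lesion_ratings$case_id, sum)
    if (any(abs(ws - 1) > 1e-6))
      stop_validation("per-case lesion weights must sum to 1")
  }
  structure(list(lesion_ratings = lesion_ratings, nl = nl, cases = cases,
                 K_N = sum(cases$n_lesions > 0),
                 K_F = sum(cases$n_lesions == 0)),
            class = "matched_ratings")
}

#' @export
print.matched_ratings <- function(x, ...) {
  cat(sprintf(
    "<matched_ratings> %d lesions over %d diseased + %d normal cases; %d NL marks\n",
    nrow(x$lesion_ratings), x$K_N, x$K_F, nrow(x$nl)))
  invisible(x)
}

# accept a study_set, a manifest list, or a lesions tibble (+ cases)
as_manifest <- function(x, cases = NULL) {
  if (inherits(x, "study_set")) return(x$manifest)
  if (is.list(x) && !is.data.frame(x) && all(c("cases", "lesions") %in% names(x)))
    return(x)
  if (is.data.frame(x)) {
    if (is.null(cases)) {
      cases <- dplyr::count(x, .data$case_id, name = "n_lesions")
    }
    return(list(cases = as_tibble(cases), lesions = as_tibble(x)))
  }
  stop_validation("cannot interpret the lesion manifest")
}

#' Match detection marks against ground-truth lesions
#'
#' A mark can localise a lesion when the Euclidean distance between the
#' mark and the lesion's ground-truth centre of mass is below `radius_px`
#' (strictly, by default — a mark at exactly the radius is a non-lesion
#' localisation). Candidate pairs are matched greedily one-to-one in order
#' of descending mark score, ties broken by smaller distance then smaller
#' `lesion_id`. Matched marks' scores become the lesion ratings; unmatched
#' marks are non-lesion (false positive) localisations; lesions without a
#' match are unmarked (`-Inf` rating).
#'
#' @param marks tibble/data frame with `case_id`, `x`, `y`, `score`.
#'   Duplicated `(case_id, x, y, score)` rows are collapsed with a warning.
#' @param manifest a `study_set`, a manifest list (`cases` + `lesions`
#'   tibbles), or a lesions tibble (case roster then inferred from it, or
#'   supplied via `cases`).
#' @param radius_px matching radius in output pixels (default 30).
#' @param score_threshold optional ζ; marks with score below it are
#'   discarded before matching.
#' @param radius_inclusive treat a distance exactly equal to `radius_px`
#'   as a match (default `FALSE`: strict "below").
#' @param cases optional case roster when `manifest` is a bare lesions
#'   table.
#' @return a [matched_ratings()].
#' @export
match_marks <- function(marks, manifest, radius_px = 30,
                        score_threshold = NULL, radius_inclusive = FALSE,
                        cases = NULL) {
  man <- as_manifest(manifest, cases)
  marks <- as_tibble(marks)
  need <- c("case_id", "x", "y", "score")
  if (!all(need %in% names(marks)))
    stop_validation("marks need columns case_id, x, y, score")
  if (nrow(marks) && any(!is.finite(marks$score)))
    stop_validation("mark scores must be finite")
  unknown <- setdiff(unique(marks$case_id), man$cases$case_id)
  if (length(unknown))
    stop_validation(paste("marks reference unknown case(s):",
                          paste(unknown, collapse = ", ")))
  dup <- duplicated(marks[, need])
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate mark(s)", sum(dup)),
         class = "cxrsim_duplicate_marks_warning")
    marks <- marks[!dup, ]
  }
  if (!is.null(score_threshold))
    marks <- marks[marks$score >= score_threshold, , drop = FALSE]
  lesions <- man$lesions
  marks$.mark <- seq_len(nrow(marks))
  matched_mark <- rep(NA_integer_, nrow(lesions))
  mark_used <- rep(FALSE, nrow(marks))
  if (nrow(marks) && nrow(lesions)) {
    cand <- dplyr::inner_join(marks, lesions, by = "case_id",
                              relationship = "many-to-many")
    cand$dist <- sqrt((cand$x - cand$com_x)^2 + (cand$y - cand$com_y)^2)
    keep <- if (radius_inclusive) cand$dist <= radius_px
            else cand$dist < radius_px
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      cand$.lesion <- match(paste(cand$case_id, cand$lesion_id),
                            paste(lesions$case_id, lesions$lesion_id))
      cand <- cand[order(-cand$score, cand$dist, cand$lesion_id), ]
      for (r in seq_len(nrow(cand))) {
        mi <- cand$.mark[r]; li <- cand$.lesion[r]
        if (!mark_used[mi] && is.na(matched_mark[li])) {
          matched_mark[li] <- mi
          mark_used[mi] <- TRUE
        }
      }
    }
  }
  rating <- ifelse(is.na(matched_mark), -Inf, marks$score[matched_mark])
  weight <- if ("weight" %in% names(lesions)) lesions$weight
            else stats::ave(lesions$lesion_id, lesions$case_id,
                            FUN = function(v) rep(1 / length(v), length(v)))
  lr <- tibble(case_id = lesions$case_id, lesion_id = lesions$lesion_id,
               weight = weight, rating = rating)
  nl <- tibble(case_id = marks$case_id[!mark_used],
               score = marks$score[!mark_used])
  matched_ratings(lr, nl, man$cases[, c("case_id", "n_lesions")])
}

#' Equal per-case lesion weights
#'
#' Every lesion in a case carries the same weight `1/n_lesions`, so the
#' weights sum to one per case and each patient contributes equally to the
#' weighted lesion localisation fraction.
#'
#' @param n_lesions number of lesions in the case, >= 1.
#' @return numeric vector of length `n_lesions` summing to 1.
#' @export
lesion_weights <- function(n_lesions) {
  if (length(n_lesions) != 1L || is.na(n_lesions) || n_lesions < 1)
    stop_validation("n_lesions must be a single integer >= 1")
  rep(1 / n_lesions, n_lesions)
}

#' FROC curve
#'
#' For each distinct score ζ (descending), the lesion localisation fraction
#' `LLF(ζ) = #\{lesion ratings >= ζ\} / total lesions` and the non-lesion
#' localisation fraction `NLF(ζ) = #\{false-positive marks >= ζ\} / total
#' cases` (nodule-containing plus nodule-free).
#'
#' @param ratings a [matched_ratings()].
#' @return tibble of class `froc_curve` with columns `zeta`, `llf`, `nlf`.
#' @export
compute_froc <- function(ratings) {
  stopifnot(inherits(ratings, "matched_ratings"))
  n_lesions <- nrow(ratings$lesion_ratings)
  if (n_lesions == 0L) stop_validation("no lesions in the manifest")
  n_cases <- nrow(ratings$cases)
  z <- ratings$lesion_ratings$rating
  fp <- ratings$nl$score
  zeta <- sort(unique(c(z[is.finite(z)], fp)), decreasing = TRUE)
  if (length(zeta) == 0L) {
    # no marks at all: the curve degenerates to the single point (0, 0)
    curve <- tibble(zeta = Inf, llf = 0, nlf = 0)
  } else {
    curve <- tibble(
      zeta = zeta,
      llf = vapply(zeta, function(t) sum(z >= t), 0) / n_lesions,
      nlf = vapply(zeta, function(t) sum(fp >= t), 0) / n_cases)
  }
  structure(curve, class = c("froc_curve", class(curve)),
            n_lesions = n_lesions, n_cases = n_cases)
}

# psi kernel of the Wilcoxon-type figure of merit (ties count 1/2)
psi_kernel <- function(a, b) (b > a) + 0.5 * (b == a)

# highest false-positive score per nodule-free case; -Inf when the case
# carries no mark at all
fp_per_normal_case <- function(ratings) {
  normal <- ratings$cases$case_id[ratings$cases$n_lesions == 0]
  fp <- rep(-Inf, length(normal))
  names(fp) <- normal
  if (nrow(ratings$nl)) {
    on_normal <- ratings$nl[ratings$nl$case_id %in% normal, ]
    if (nrow(on_normal)) {
      mx <- tapply(on_normal$score, on_normal$case_id, max)
      fp[names(mx)] <- mx
    }
  }
  fp
}

#' Weighted AFROC analysis
#'
#' Computes the wAFROC operating points and figure of merit. For a
#' threshold ζ the weighted lesion localisation fraction is
#' \deqn{wLLF(\zeta) = \frac{1}{K_N} \sum_{k=1}^{K_N} \sum_{l=1}^{L_k}
#'   W_{kl}\, I(z_{kl} \ge \zeta)}
#' and the false positive fraction, over nodule-free cases only, is
#' \deqn{FPF(\zeta) = \frac{1}{K_F} \sum_{k=1}^{K_F} I(FP_k \ge \zeta)}
#' with \eqn{FP_k} the highest false-positive score on nodule-free case
#' \eqn{k}. The figure of merit is the weighted two-sample statistic
#' \deqn{FOM = \frac{1}{K_N K_F} \sum_{k' \in normal} \sum_{k \in diseased}
#'   \sum_l W_{kl}\, \psi(FP_{k'}, z_{kl})}
#' with \eqn{\psi(a,b)} equal to 1 when `b > a`, 1/2 when `b = a` and 0
#' otherwise; unmarked lesions and mark-free normal cases rate `-Inf`, so
#' two "no mark" values tie at 1/2. This equals the trapezoidal area under
#' the empirical wAFROC curve extended to (1, 1).
#'
#' @param ratings a [matched_ratings()] with at least one diseased and one
#'   nodule-free case.
#' @return object of class `wafroc_result`: `curve` (tibble `zeta`, `fpf`,
#'   `wllf`), `fom`, `K_N`, `K_F`.
#' @export
compute_wafroc <- function(ratings) {
  stopifnot(inherits(ratings, "matched_ratings"))
  if (ratings$K_N < 1)
    stop_validation("wAFROC needs at least one nodule-containing case")
  if (ratings$K_F < 1)
    stop_validation("wAFROC needs nodule-free cases (K_F = 0)")
  lr <- ratings$lesion_ratings
  fp <- fp_per_normal_case(ratings)
  z <- lr$rating; w <- lr$weight
  zeta <- sort(unique(c(z[is.finite(z)], fp[is.finite(fp)])),
               decreasing = TRUE)
  curve <- tibble(
    zeta = zeta,
    fpf = vapply(zeta, function(t) sum(fp >= t), 0) / ratings$K_F,
    wllf = vapply(zeta, function(t) sum(w * (z >= t)), 0) / ratings$K_N)
  # psi-kernel figure of merit; -Inf vs -Inf ties contribute 1/2
  contrib <- vapply(fp, function(a) sum(w * psi_kernel(a, z)), 0)
  fom <- sum(contrib) / (ratings$K_N * ratings$K_F)
  structure(list(curve = curve, fom = fom,
                 K_N = ratings$K_N, K_F = ratings$K_F,
                 n_lesions = nrow(lr)),
            class = "wafroc_result")
}

#' @export
print.wafroc_result <- function(x, ...) {
  cat(sprintf("<wafroc_result> FOM = %.4f (K_N = %d, K_F = %d, %d lesions)\n",
              x$fom, x$K_N, x$K_F, x$n_lesions))
  invisible(x)
}

# vertices of the empirical wAFROC curve: (0,0), the operating points in
# descending-zeta order, and the (1,1) extension
wafroc_vertices <- function(result) {
  v <- rbind(c(0, 0),
             cbind(result$curve$fpf, result$curve$wllf),
             c(1, 1))
  colnames(v) <- c("fpf", "wllf")
  v
}

#' Trapezoidal area under the empirical wAFROC curve
#'
#' Independent of the ψ-kernel formula; used as a cross-check of
#' [compute_wafroc()]'s figure of merit.
#'
#' @param result a `wafroc_result`.
#' @return scalar area.
#' @export
wafroc_curve_area <- function(result) {
  v <- wafroc_vertices(result)
  sum(diff(v[, 1]) * (head(v[, 2], -1) + tail(v[, 2], -1)) / 2)
}

#' Interpolate wLLF at a false-positive-fraction operating point
#'
#' Linear interpolation along the empirical wAFROC curve (its upper
#' envelope at vertical jumps), from (0, 0) through the operating points to
#' the (1, 1) extension.
#'
#' @param result a `wafroc_result`.
#' @param fpf requested operating point in \[0, 1\] (0.2 is the
#'   conventional reporting point).
#' @return interpolated wLLF.
#' @export
wllf_at <- function(result, fpf = 0.2) {
  stopifnot(inherits(result, "wafroc_result"))
  if (fpf < 0 || fpf > 1) stop_validation("fpf must lie in [0, 1]")
  v <- wafroc_vertices(result)
  # follow the curve path: at each distinct FPF the curve enters at the
  # lowest wLLF and leaves at the highest (vertical jump); an exact query
  # returns the point's (upper) wLLF, an interior query interpolates from
  # the left x's upper value to the right x's lower value
  xs <- sort(unique(v[, 1]))
  y_hi <- vapply(xs, function(x) max(v[v[, 1] == x, 2]), 0)
  y_lo <- vapply(xs, function(x) min(v[v[, 1] == x, 2]), 0)
  hit <- which(xs == fpf)
  if (length(hit)) return(y_hi[hit])
  i <- findInterval(fpf, xs)
  y_hi[i] + (fpf - xs[i]) / (xs[i + 1] - xs[i]) * (y_lo[i + 1] - y_hi[i])
}

#' Count true/false positives and false negatives at a threshold
#'
#' `TP` is the number of lesions whose rating passes ζ, `FN` the remainder,
#' and `FP` the number of non-lesion marks passing the same comparison. The
#' default comparison is `>=` (the reader convention); `strict = TRUE`
#' uses `>` (the convention for thresholding detector confidence at 0.5).
#'
#' @param ratings a [matched_ratings()].
#' @param zeta score threshold.
#' @param strict use `>` instead of `>=`.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
summarize_counts <- function(ratings, zeta, strict = FALSE) {
  stopifnot(inherits(ratings, "matched_ratings"))
  cmp <- if (strict) `>` else `>=`
  z <- ratings$lesion_ratings$rating
  tp <- sum(cmp(z, zeta))
  fp <- sum(cmp(ratings$nl$score, zeta))
  c(tp = tp, fp = fp, fn = length(z) - tp)
}

#' Combine box detections with segmentation marks
#'
#' A bounding box is retained if and only if at least one segmentation mark
#' lies inside it (edges inclusive); each retained box becomes a mark at
#' its centre carrying the box's score. This is the standard rule for
#' fusing a box detector with a segmenter: the box's confidence is kept,
#' the segmenter acts as a verifier.
#'
#' @param boxes tibble with `case_id`, `x0`, `y0`, `x1`, `y1`, `score`
#'   (corners with `x0 < x1`, `y0 < y1`).
#' @param seg_marks tibble of marks (`case_id`, `x`, `y`, ...).
#' @return tibble of marks (`case_id`, `x`, `y`, `score`).
#' @export
combine_detections <- function(boxes, seg_marks) {
  boxes <- as_tibble(boxes)
  seg_marks <- as_tibble(seg_marks)
  if (nrow(boxes) && any(boxes$x0 >= boxes$x1 | boxes$y0 >= boxes$y1))
    stop_validation("degenerate box: need x0 < x1 and y0 < y1")
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    s <- seg_marks[seg_marks$case_id == boxes$case_id[i], ]
    keep[i] <- any(s$x >= boxes$x0[i] & s$x <= boxes$x1[i] &
                   s$y >= boxes$y0[i] & s$y <= boxes$y1[i])
  }
  tibble(case_id = boxes$case_id[keep],
         x = (boxes$x0[keep] + boxes$x1[keep]) / 2,
         y = (boxes$y0[keep] + boxes$y1[keep]) / 2,
         score = boxes$score[keep])
}

#' Turn a segmentation mask into marks
#'
#' One mark per 8-connected component of the binary mask, located at the
#' component's centre of mass (0-based pixel coordinates, `x` = column,
#' `y` = row). The score is the maximum of `score_image` over the
#' component, or 1 when no score image is given.
#'
#' @param mask binary matrix.
#' @param score_image optional numeric matrix of per-pixel scores, same
#'   shape as `mask`.
#' @param case_id case label attached to the marks.
#' @return tibble of marks; empty for an empty mask.
#' @export
marks_from_segmentation <- function(mask, score_image = NULL,
                                    case_id = "case") {
  stopifnot(is.matrix(mask))
  if (!is.null(score_image)) stopifnot(identical(dim(score_image), dim(mask)))
  m3 <- array(mask != 0, c(nrow(mask), ncol(mask), 1L))
  lab <- .cc_label(as.logical(m3), dim(m3), 26L)   # 8-connectivity in-plane
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L)
    return(tibble(case_id = character(), x = numeric(), y = numeric(),
                  score = numeric()))
  lab <- array(lab, dim(mask))
  out <- lapply(seq_len(ncomp), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    tibble(case_id = case_id,
           x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1,
           score = if (is.null(score_image)) 1
                   else max(score_image[idx]))
  })
  bind_rows(out)
}

# ---------------------------------------------------------------------------
# Truth/NL/LL rating tables (the layout used by observer-performance
# software: Truth sheet with CaseID/LesionID/Weight where LesionID 0 marks
# a normal case; NL sheet with per-mark non-lesion ratings; LL sheet with
# per-lesion ratings)

read_rating_sheets <- function(path) {
  if (dir.exists(path)) {
    find1 <- function(nm) {
      hits <- list.files(path, pattern = paste0("^", nm, "\\.csv$"),
                         ignore.case = TRUE, full.names = TRUE)
      if (!length(hits)) stop_io(paste("missing", nm, "table in", path))
      read.csv(hits[1], stringsAsFactors = FALSE)
    }
    list(truth = find1("Truth"), nl = find1("NL"), ll = find1("LL"))
  } else if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_io("reading .xlsx rating tables requires the readxl package")
    sheets <- readxl::excel_sheets(path)
    pick <- function(nm) {
      i <- match(tolower(nm), tolower(sheets))
      if (is.na(i)) stop_format(paste("workbook lacks sheet", nm))
      as.data.frame(readxl::read_excel(path, sheet = sheets[i]))
    }
    list(truth = pick("Truth"), nl = pick("NL"), ll = pick("LL"))
  } else stop_format("rating table must be a directory of CSVs or an .xlsx file")
}

norm_names <- function(df) {
  names(df) <- tolower(gsub("[^A-Za-z]", "", names(df)))
  df
}

#' Load a Truth/NL/LL rating table
#'
#' Reads the three-table observer-rating layout from a directory containing
#' `Truth.csv`, `NL.csv` and `LL.csv`, or from an `.xlsx` workbook with
#' sheets of those names. Truth columns: `CaseID`, `LesionID` (0 marks a
#' nodule-free case), `Weight`; NL: `ReaderID`, `ModalityID`, `CaseID`,
#' `NL_Rating`; LL: `ReaderID`, `ModalityID`, `CaseID`, `LesionID`,
#' `LL_Rating`. Weights of diseased cases must sum to one (within 1e-6);
#' LL rows must reference known lesions.
#'
#' @param path directory or `.xlsx` path.
#' @return object of class `rating_table`: tibbles `truth`, `nl`, `ll` and
#'   the reader/modality combinations present.
#' @export
load_rating_table <- function(path) {
  sheets <- read_rating_sheets(path)
  truth <- norm_names(sheets$truth)
  nl <- norm_names(sheets$nl)
  ll <- norm_names(sheets$ll)
  need <- function(df, cols, where) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_format(paste0(where, " table lacks column(s): ",
                         paste(miss, collapse = ", ")))
  }
  need(truth, c("caseid", "lesionid", "weight"), "Truth")
  need(nl, c("readerid", "modalityid", "caseid", "nlrating"), "NL")
  need(ll, c("readerid", "modalityid", "caseid", "lesionid", "llrating"), "LL")
  truth$caseid <- as.character(truth$caseid)
  nl$caseid <- as.character(nl$caseid)
  ll$caseid <- as.character(ll$caseid)
  diseased <- truth[truth$lesionid > 0, ]
  if (nrow(diseased)) {
    ws <- tapply(diseased$weight, diseased$caseid, sum)
    bad <- names(ws)[abs(ws - 1) > 1e-6]
    if (length(bad))
      stop_validation(paste("lesion weights do not sum to 1 for case(s):",
                            paste(bad, collapse = ", ")))
  }
  key <- paste(diseased$caseid, diseased$lesionid)
  bad_ll <- !paste(ll$caseid, ll$lesionid) %in% key
  if (any(bad_ll))
    stop_validation(paste("LL row(s) reference unknown lesions:",
                          paste(unique(paste(ll$caseid[bad_ll],
                                             ll$lesionid[bad_ll])),
                                collapse = ", ")))
  unknown_nl <- !nl$caseid %in% truth$caseid
  if (any(unknown_nl))
    stop_validation("NL row(s) reference unknown cases")
  structure(list(truth = as_tibble(truth), nl = as_tibble(nl),
                 ll = as_tibble(ll),
                 readers = unique(c(nl$readerid, ll$readerid)),
                 modalities = unique(c(nl$modalityid, ll$modalityid))),
            class = "rating_table")
}

#' Write a Truth/NL/LL rating table as CSVs
#'
#' @param table a `rating_table` (or a list with `truth`, `nl`, `ll`).
#' @param dir output directory.
#' @export
write_rating_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(table$truth, file.path(dir, "Truth.csv"), row.names = FALSE)
  write.csv(table$nl, file.path(dir, "NL.csv"), row.names = FALSE)
  write.csv(table$ll, file.path(dir, "LL.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Matched ratings for one reader/modality of a rating table
#'
#' @param table a `rating_table` from [load_rating_table()].
#' @param reader reader id (defaults to the first present).
#' @param modality modality id (defaults to the first present).
#' @return a [matched_ratings()].
#' @export
ratings_from_table <- function(table, reader = NULL, modality = NULL) {
  stopifnot(inherits(table, "rating_table"))
  if (is.null(reader)) reader <- table$readers[1]
  if (is.null(modality)) modality <- table$modalities[1]
  truth <- table$truth
  diseased <- truth[truth$lesionid > 0, ]
  n_les <- tapply(diseased$lesionid, diseased$caseid, length)
  cases <- tibble(case_id = unique(truth$caseid))
  cases$n_lesions <- ifelse(cases$case_id %in% names(n_les),
                            as.integer(n_les[cases$case_id]), 0L)
  ll <- table$ll[table$ll$readerid == reader &
                 table$ll$modalityid == modality, ]
  nl <- table$nl[table$nl$readerid == reader &
                 table$nl$modalityid == modality, ]
  key <- paste(ll$caseid, ll$lesionid)
  lkey <- paste(diseased$caseid, diseased$lesionid)
  rating <- rep(-Inf, nrow(diseased))
  hit <- match(lkey, key)
  rating[!is.na(hit)] <- ll$llrating[hit[!is.na(hit)]]
  lr <- tibble(case_id = diseased$caseid, lesion_id = diseased$lesionid,
               weight = diseased$weight, rating = rating)
  matched_ratings(lr, tibble(case_id = nl$caseid, score = nl$nlrating),
                  cases)
}

# ---------------------------------------------------------------------------
# tidiers and plots

#' @export
tidy.wafroc_result <- function(x, ...) x$curve

#' @export
glance.wafroc_result <- function(x, ...) {
  tibble(fom = x$fom, curve_area = wafroc_curve_area(x),
         K_N = x$K_N, K_F = x$K_F, n_lesions = x$n_lesions)
}

#' @export
tidy.froc_curve <- function(x, ...) as_tibble(x)

#' @export
autoplot.froc_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nlf, y = .data$llf)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "non-lesion localisations per case (NLF)",
                  y = "lesion localisation fraction (LLF)",
                  title = "FROC curve")
}

#' @export
autoplot.wafroc_result <- function(object, ...) {
  v <- as.data.frame(wafroc_vertices(object))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$fpf, y = .data$wllf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tidy(object),
                        ggplot2::aes(x = .data$fpf, y = .data$wllf),
                        size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive fraction (FPF)",
                  y = "weighted lesion localisation fraction (wLLF)",
                  title = sprintf("wAFROC (FOM = %.3f)", object$fom))
}

#' @export
autoplot.radiograph <- function(object, ...) {
  img <- display_radiograph(object)$pixels
  df <- expand.grid(y = seq_len(nrow(img)) - 1, x = seq_len(ncol(img)) - 1)
  df$value <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
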