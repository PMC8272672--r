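#' Build an injury-grade contingency table
#'
#' Grades follow the four-level MRI scale: grade 0 no abnormality, grade
#' I partial damage under 50\%, grade II damage of 50\% or more, grade
#' III complete rupture. Both modalities grade the same knees, so totals
#' must agree.
#'
#' @param counts 2 x 4 matrix of knee counts (rows = modalities, columns
#'   = grades 0, I, II, III), or two length-4 vectors via \code{...}.
#' @param modalities row names; default MRI and arthroscopy.
#' @return a \linkS4class{GradeTable}.
#' @examples
#' gt <- gradeTable(rbind(c(34, 10, 10, 6), c(34, 13, 11, 2)))
#' chiSquareTest(counts(gt))
#' @export
gradeTable <- function(counts, modalities = c("MRI", "arthroscopy")) {
  m <- matrix(as.integer(counts), 2L, 4L,
              dimnames = list(modalities, c("grade0", "gradeI", "gradeII", "gradeIII")))
  new("GradeTable", counts = m)
}

#' @describeIn GradeTable-class the 2 x 4 count matrix.
#' @export
setMethod("counts", "GradeTable", function(object) object@counts)

setMethod("show", "GradeTable", function(object) {
  cat("GradeTable (knees per injury grade)\n")
  print(object@counts)
})

#' Read a grade table from CSV
#'
#' Expected columns: \code{modality}, \code{grade0}, \code{gradeI},
#' \code{gradeII}, \code{gradeIII}; exactly two rows.
#'
#' @param path CSV path.
#' @return a \linkS4class{GradeTable}.
#' @export
readGradeTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "grade0", "gradeI", "gradeII", "gradeIII")
  if (!all(need %in% names(d)) || nrow(d) != 2L)
    stop("grade table CSV needs two rows and columns ",
         paste(need, collapse = ", "))
  gradeTable(as.matrix(d[, need[-1]]), modalities = d$modality)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction by
#' default), df = (rows-1)(cols-1), p-value from the upper chi-square
#' tail. Every expected count must be positive.
#'
#' @param table numeric matrix of counts (e.g. 2 x k).
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}.
#' @export
chiSquareTest <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) {
    bad <- which(expected <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("expected count is zero in cell (%d, %d)", bad[1], bad[2]))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value), expected = expected)
}

#' Diagnostic agreement of an index test against a reference
#'
#' Binarizes paired grades with grade 0 as the sole negative class
#' (grades I-III positive) and computes sensitivity, specificity and
#' accuracy of the index modality against the reference via the binary
#' confusion counts. Grades may be given as \code{0, "I", "II", "III"} or
#' as integers 0-3.
#'
#' @param index,reference equal-length grade vectors.
#' @return list with the three metrics (NA-flagged when a denominator is
#'   zero) and the underlying \linkS4class{ConfusionMatrix}.
#' @export
diagnosticStats <- function(index, reference) {
  toBin <- function(g) {
    g <- as.character(g)
    ok <- g %in% c("0", "I", "II", "III", "1", "2", "3")
    if (!all(ok)) stop("invalid grade(s): ", paste(unique(g[!ok]), collapse = ", "))
    as.integer(g != "0")
  }
  if (!length(index)) stop("empty grade vectors")
  cm <- confusionCounts(toBin(index), toBin(reference))
  list(sensitivity = sensitivity(cm), specificity = specificity(cm),
       accuracy = accuracy(cm), confusion = cm)
}

#' Concomitant-injury positive rates for acute vs chronic groups
#'
#' Rates are positives/size per group; the association p-value comes from
#' the (uncorrected) chi-square on the 2 x 2 positives/negatives table.
#'
#' @param acutePos,acuteN positives and group size in the acute group.
#' @param chronicPos,chronicN same for the chronic group.
#' @return list with \code{acuteRate}, \code{chronicRate} (proportions)
#'   and \code{p.value}.
#' @export
positiveRates <- function(acutePos, acuteN, chronicPos, chronicN) {
  stopifnot(acutePos <= acuteN, chronicPos <= chronicN, acuteN > 0, chronicN > 0)
  tab <- rbind(c(acutePos, acuteN - acutePos),
               c(chronicPos, chronicN - chronicPos))
  list(acuteRate = acutePos / acuteN, chronicRate = chronicPos / chronicN,
       p.value = chiSquareTest(tab)$p.value)
}

#' Read concomitant-injury counts from CSV
#'
#' Expected columns: \code{category}, \code{acute_pos}, \code{acute_n},
#' \code{chronic_pos}, \code{chronic_n}.
#'
#' @param path CSV path.
#' @return data.frame of validated counts.
#' @export
readConcomitantCounts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "acute_pos", "acute_n", "chronic_pos", "chronic_n")
  if (!all(need %in% names(d)))
    stop("concomitant CSV needs columns ", paste(need, collapse = ", "))
  if (any(d$acute_pos > d$acute_n) || any(d$chronic_pos > d$chronic_n))
    stop("positives exceed group size")
  d
}
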