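## ISNCSCI/SCIM clinical layer: typed cohort tables, neurological-level
## derivation from dermatome/myotome exams, lesion completeness, and the
## cohort summary statistics.

#' Canonical spinal segment ordering (rostral to caudal)
#'
#' C1..C8, T1..T12, L1..L5, S1..S5 (S5 standing for the S4-5 dermatome).
#'
#' @return character vector of segment labels.
#' @export
spinalSegments <- function() {
  c(paste0("C", 1:8), paste0("T", 1:12), paste0("L", 1:5), paste0("S", 1:5))
}

#' ISNCSCI sensory dermatomes (C2..S4-5)
#' @return character vector.
#' @export
sensoryDermatomes <- function() {
  c(paste0("C", 2:8), paste0("T", 1:12), paste0("L", 1:5), paste0("S", 1:3), "S4-5")
}

#' ISNCSCI key myotomes (C5..T1, L2..S1)
#' @return character vector.
#' @export
keyMyotomes <- function() c(paste0("C", 5:8), "T1", paste0("L", 2:5), "S1")

scoreBounds <- list(lems = c(0, 50), uems = c(0, 50), pp = c(0, 112),
                    lt = c(0, 112), scim = c(0, 100))

#' Read and validate a clinical cohort table
#'
#' Typed ingestion of a cohort CSV (one row per patient) with the schema
#' `id, age, tsi_months, completeness, ais, motor_site, sensory_site, lems,
#' uems, pp, lt, scim` (case-insensitive header). `"NA"` entries become
#' missing values; rows with out-of-bounds scores or malformed segment labels
#' are rejected with a message.
#'
#' @param path CSV file path.
#' @return data.frame of validated records with attributes `nMissing`
#'   (missing values per column). An empty file yields an empty data.frame
#'   with a warning.
#' @examples
#' tab <- readCohortTable(system.file("extdata", "table1_cohort.csv",
#'                                    package = "qmriMorph"))
#' nrow(tab)   # 30
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("id", "age", "tsi_months", "completeness", "ais",
            "motor_site", "sensory_site", "lems", "uems", "pp", "lt", "scim")
  if (nrow(tab) == 0) {
    warning("empty cohort table")
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(need))), need))
  }
  if (!all(need %in% names(tab)))
    stop("cohort table header must contain: ", paste(need, collapse = ", "))
  tab <- tab[need]
  for (nm in c("age", "tsi_months", names(scoreBounds)))
    tab[[nm]] <- suppressWarnings(as.numeric(tab[[nm]]))
  if (any(!is.na(tab$tsi_months) & tab$tsi_months <= 0))
    stop("tsi_months must be positive")
  segs <- spinalSegments()
  for (nm in c("motor_site", "sensory_site")) {
    bad <- !is.na(tab[[nm]]) & !tab[[nm]] %in% segs
    if (any(bad))
      stop("malformed segment label in ", nm, ": ",
           paste(unique(tab[[nm]][bad]), collapse = ", "))
  }
  if (any(!tab$ais %in% c("A", "B", "C", "D", "E")))
    stop("ais must be one of A-E")
  for (nm in names(scoreBounds)) {
    b <- scoreBounds[[nm]]
    bad <- !is.na(tab[[nm]]) & (tab[[nm]] < b[1] | tab[[nm]] > b[2])
    if (any(bad))
      stop(sprintf("row(s) %s: %s out of bounds [%g, %g]",
                   paste(tab$id[bad], collapse = ","), nm, b[1], b[2]))
  }
  attr(tab, "nMissing") <- vapply(tab, function(v) sum(is.na(v)), integer(1))
  tab
}

#' Write a cohort table (round-trips with [readCohortTable()])
#'
#' @param tab validated cohort data.frame.
#' @param path output CSV path.
#' @export
writeCohortTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Derive sensory/motor levels and the neurological level of injury
#'
#' The sensory level is the most caudal dermatome with intact light-touch and
#' pinprick sensation (2/2 points) such that all rostral dermatomes are also
#' intact. The motor level is the most caudal key myotome graded at least 3/5
#' with all rostral key myotomes graded 5, provided sensation rostral to it
#' is intact; over segments without a key muscle the motor level follows the
#' sensory level (standard ISNCSCI convention). The neurological level of
#' injury (NLI) is the most rostral of the two.
#'
#' @param exam list with named numeric vectors `lt`, `pp` (per dermatome,
#'   values 0/1/2, names from [sensoryDermatomes()]) and `motor` (per key
#'   myotome, values 0..5, names from [keyMyotomes()]).
#' @return list with `sensory_level`, `motor_level`, `nli` (segment labels,
#'   or `"none"` when no dermatome is intact).
#' @export
deriveLevels <- function(exam) {
  derm <- sensoryDermatomes()
  lt <- exam$lt[derm]; pp <- exam$pp[derm]
  if (any(is.na(lt)) || any(is.na(pp)))
    stop("exam incomplete: light-touch/pinprick must cover all dermatomes")
  if (any(lt < 0 | lt > 2) || any(pp < 0 | pp > 2))
    stop("sensory scores must lie in {0, 1, 2}")
  intact <- stats::setNames(lt == 2 & pp == 2, derm)
  sensIdx <- if (intact[1]) max(which(cumsum(!intact) == 0)) else 0L
  sensory <- if (sensIdx == 0L) "none" else derm[sensIdx]
  ## motor: walk key myotomes; segments above the candidate must be grade 5
  myo <- keyMyotomes()
  grades <- stats::setNames(exam$motor[myo], myo)
  if (any(is.na(grades))) stop("exam incomplete: all key myotomes required")
  if (any(grades < 0 | grades > 5)) stop("motor grades must lie in 0..5")
  segs <- spinalSegments()
  segRank <- stats::setNames(seq_along(segs), segs)
  sensRank <- if (sensory == "none") 0L
              else segRank[[if (sensory == "S4-5") "S5" else sensory]]
  ## walk the upper key-muscle block; in the thoracic key-muscle gap the
  ## motor level follows the sensory exam; the lower block is reached only
  ## when everything rostral is normal
  upper <- c(paste0("C", 5:8), "T1")
  lower <- c(paste0("L", 2:5), "S1")
  gapDerms <- paste0("T", 2:12)                     # T2..T12, then L1
  gapDerms <- c(gapDerms, "L1")
  motor <- "none"
  i <- 1L
  while (i <= length(upper) && grades[upper[i]] >= 3) {
    motor <- upper[i]
    if (grades[upper[i]] < 5) break
    i <- i + 1L
  }
  if (i > length(upper)) {                          # upper block fully normal
    for (dseg in gapDerms) {
      if (!intact[dseg]) break
      motor <- dseg
    }
    if (motor == "L1") {
      j <- 1L
      while (j <= length(lower) && grades[lower[j]] >= 3) {
        motor <- lower[j]
        if (grades[lower[j]] < 5) break
        j <- j + 1L
      }
    }
  }
  motorRank <- if (motor == "none") 0L else segRank[[motor]]
  nli <- if (sensory == "none" || motor == "none") "none"
         else segs[min(sensRank, motorRank)]
  if (identical(nli, "S5") && sensory == "S4-5") nli <- "S4-5"
  list(sensory_level = sensory, motor_level = motor, nli = nli)
}

#' Lesion completeness from the AIS grade
#'
#' A lesion is complete iff no sensory or motor function is preserved in the
#' sacral segments S4-S5, i.e. AIS grade A.
#'
#' @param record list or one-row data.frame with an `ais` field.
#' @return `"complete"` or `"incomplete"`.
#' @export
classifyCompleteness <- function(record) {
  ais <- if (is.list(record) || is.data.frame(record)) record$ais else record
  if (is.na(ais) || !ais %in% c("A", "B", "C", "D", "E")) stop("ais missing or invalid")
  if (ais == "A") "complete" else "incomplete"
}

#' Cohort summary statistics
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator) and range per
#' measure over non-missing values; time since injury is reported in years.
#' Values are kept at full precision; rounding is presentational only.
#'
#' @param tab cohort data.frame from [readCohortTable()].
#' @return data.frame with rows per measure and columns `measure, n, mean,
#'   sd, min, max`.
#' @examples
#' tab <- readCohortTable(system.file("extdata", "table1_cohort.csv",
#'                                    package = "qmriMorph"))
#' summarizeCohort(tab)   # mean UEMS 42.4, mean SCIM 57.9 over n = 29, ...
#' @export
summarizeCohort <- function(tab) {
  stopifnot(nrow(tab) >= 1)
  vals <- list(age_years = tab$age,
               tsi_years = tab$tsi_months / 12,
               lems = tab$lems, uems = tab$uems,
               pp = tab$pp, lt = tab$lt, scim = tab$scim)
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]][!is.na(vals[[nm]])]
    if (!length(v))
      return(data.frame(measure = nm, n = 0L, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_))
    data.frame(measure = nm, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}

#' Tetraplegia/paraplegia counts under both site conventions
#'
#' A cervical neurological level implies tetraplegia. The tabulated motor and
#' sensory impairment sites can disagree about cervical involvement, so both
#' counts are surfaced: by motor site alone, and by cervical involvement of
#' either site.
#'
#' @param tab cohort data.frame.
#' @return named integer vector `tetra_motor`, `tetra_either`, `n`.
#' @export
tetraParaCounts <- function(tab) {
  cerv <- function(s) !is.na(s) & grepl("^C", s)
  c(tetra_motor = sum(cerv(tab$motor_site)),
    tetra_either = sum(cerv(tab$motor_site) | cerv(tab$sensory_site)),
    n = nrow(tab))
}
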