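#' Longitudinal trial data with time-dependent departure
#'
#' Constructs a validated \code{trial_data} object for a two-arm randomised
#' trial in which control-arm participants may cross over to a one-off
#' intervention at any time.  Departure time is recorded as the grouped visit
#' \code{D} (the last visit before treatment, with \code{D = m} meaning never
#' treated) and optionally as the exact day \code{T_days}.
#'
#' @param R integer vector, randomised arm per subject (1 = intervention,
#'   0 = control).
#' @param D integer vector in \code{0..m}: last visit before treatment
#'   (grouped time).  Subjects randomised to intervention are treated just
#'   after baseline, so \code{R == 1} requires \code{D == 0}.
#' @param Y numeric matrix, \code{n x m}, outcome at post-randomisation visits
#'   \code{1..m}; \code{NA} marks a missing outcome.
#' @param visit_days numeric vector \code{t_1 < ... < t_m} of days from
#'   randomisation to each visit.
#' @param T_days optional numeric vector of exact treatment days
#'   (\code{Inf} or \code{NA} = never treated); must be consistent with
#'   \code{D}: \code{t_D < T <= t_{D+1}} with \code{t_0 = 0}.
#' @param id optional subject identifiers.
#' @param baseline optional numeric vector/matrix of pre-randomisation
#'   outcomes; stored but not modelled.
#' @param permissive logical; if \code{TRUE}, an intervention-arm subject with
#'   \code{D != 0} raises a warning instead of an error (and \code{D} is kept
#'   as given).
#'
#' @return An object of class \code{trial_data}: a list with elements
#'   \code{n}, \code{m}, \code{R}, \code{D}, \code{T_days}, \code{visit_days},
#'   \code{Y}, \code{missing_mask}, \code{id}, \code{baseline}.
#' @seealso [read_trial_csv()], [derive_compliance()], [days_to_grouped()]
#' @export
trial_data <- function(R, D, Y, visit_days, T_days = NULL, id = NULL,
                       baseline = NULL, permissive = FALSE) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  m <- ncol(Y)
  if (m < 1L) stop("Y must have at least one visit column")
  R <- as.integer(R)
  D <- as.integer(D)
  if (length(R) != n || length(D) != n)
    stop("R and D must have one entry per row of Y")
  if (!all(R %in% c(0L, 1L))) stop("R must be 0 (control) or 1 (intervention)")
  if (anyNA(D) || any(D < 0L | D > m))
    stop("D must lie in 0..m (m = ", m, " means never treated)")
  bad <- which(R == 1L & D != 0L)
  if (length(bad)) {
    msg <- paste0("subjects randomised to intervention must have D = 0 ",
                  "(treated just after baseline); offending rows: ",
                  paste(utils::head(bad, 5L), collapse = ", "))
    if (permissive) warning(msg) else stop(msg)
  }
  visit_days <- as.numeric(visit_days)
  if (length(visit_days) != m || any(visit_days <= 0) ||
      any(diff(visit_days) <= 0))
    stop("visit_days must be ", m, " strictly increasing positive days")
  if (!is.null(T_days)) {
    T_days <- as.numeric(T_days)
    if (length(T_days) != n) stop("T_days must have one entry per subject")
    T_chk <- ifelse(is.na(T_days), Inf, T_days)
    if (any(T_chk <= 0)) stop("treatment days must be positive")
    grp <- vapply(T_chk, days_to_grouped, integer(1L), visit_days = visit_days)
    off <- which(grp != D)
    if (length(off))
      stop("T_days inconsistent with grouped departure D for rows: ",
           paste(utils::head(off, 5L), collapse = ", "))
  }
  if (is.null(id)) id <- seq_len(n)
  structure(list(
    n = n, m = m, R = R, D = D, T_days = T_days,
    visit_days = visit_days, Y = Y, missing_mask = is.na(Y),
    id = id, baseline = baseline
  ), class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Longitudinal trial data:", x$n, "subjects,", x$m, "visits\n")
  cat("  arms: ", sum(x$R == 1L), " intervention / ", sum(x$R == 0L),
      " control\n", sep = "")
  tab <- table(factor(x$D[x$R == 0L], levels = 0:x$m))
  cat("  control-arm departure visits (D):",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  visit days:", paste(x$visit_days, collapse = ", "), "\n")
  cat("  missing outcomes:", sum(x$missing_mask), "of", length(x$Y), "\n")
  invisible(x)
}

#' Map an exact treatment day to its grouped departure visit
#'
#' Returns the visit index \code{c} with \code{t_c < T <= t_{c+1}}, taking
#' \code{t_0 = 0} and \code{t_{m+1} = Inf}, so a treatment recorded on a visit
#' day is grouped with that visit ("just after" the visit).  \code{Inf},
#' \code{NA} or the string \code{"never"} map to \code{m} (never treated).
#'
#' @param T treatment day (positive scalar), or \code{"never"}/\code{NA}/
#'   \code{Inf}.
#' @param visit_days strictly increasing positive day grid \code{t_1..t_m}.
#' @return integer in \code{0..m}.
#' @export
days_to_grouped <- function(T, visit_days) {
  m <- length(visit_days)
  if (is.character(T)) {
    if (identical(tolower(T), "never")) return(m) else T <- as.numeric(T)
  }
  if (is.na(T) || is.infinite(T)) return(m)
  if (T <= 0) stop("treatment day must be positive")
  sum(visit_days < T)
}

#' Observed and latent compliance types
#'
#' Compliance type \code{C} is the departure visit a subject would have under
#' randomisation to control.  It is observed (\code{C = D}) for control-arm
#' subjects and latent for intervention-arm subjects, who were treated at
#' baseline regardless of type.
#'
#' @param dataset a [trial_data] object.
#' @return list with integer vector \code{C} (\code{NA} where latent) and
#'   logical vector \code{known}.
#' @export
derive_compliance <- function(dataset) {
  stopifnot(inherits(dataset, "trial_data"))
  known <- dataset$R == 0L
  C <- ifelse(known, dataset$D, NA_integer_)
  list(C = as.integer(C), known = known)
}

#' Read longitudinal trial data from CSV
#'
#' Expects one row per subject with columns \code{id}, \code{R}, \code{D},
#' optional \code{T_days}, and outcome columns \code{y1..ym} (empty cells or
#' \code{NA} = missing).  Column names can be remapped through \code{schema}.
#'
#' @param path CSV file path.
#' @param visit_days day grid \code{t_1..t_m}; its length fixes \code{m}.
#' @param schema optional named list/vector mapping canonical names
#'   (\code{id}, \code{R}, \code{D}, \code{T_days}, \code{y1}, ...) to the
#'   file's column names.
#' @param permissive passed to [trial_data()].
#' @return a [trial_data] object.
#' @export
read_trial_csv <- function(path, visit_days, schema = NULL,
                           permissive = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  m <- length(visit_days)
  want <- c("id", "R", "D", "T_days", paste0("y", seq_len(m)))
  colmap <- stats::setNames(want, want)
  if (!is.null(schema)) colmap[names(schema)] <- unlist(schema)
  need <- setdiff(want, "T_days")
  missing_cols <- need[!(colmap[need] %in% names(raw))]
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(colmap[missing_cols], collapse = ", "))

  num <- function(canon) {
    col <- colmap[[canon]]
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out) & tolower(v) != "never")
    if (length(bad))
      stop("malformed numeric cell in column '", col, "', row ", bad[1L],
           ": '", v[bad[1L]], "'")
    out
  }
  Y <- sapply(paste0("y", seq_len(m)), num)
  if (nrow(raw) == 1L) Y <- matrix(Y, nrow = 1L)
  dimnames(Y) <- NULL
  Td <- NULL
  if (colmap[["T_days"]] %in% names(raw)) {
    v <- raw[[colmap[["T_days"]]]]
    Td <- ifelse(!is.na(v) & tolower(v) == "never", Inf,
                 suppressWarnings(as.numeric(v)))
    bad <- which(!is.na(v) & is.na(Td))
    if (length(bad))
      stop("malformed numeric cell in column '", colmap[["T_days"]],
           "', row ", bad[1L])
  }
  trial_data(R = num("R"), D = num("D"), Y = Y, visit_days = visit_days,
             T_days = Td, id = raw[[colmap[["id"]]]], permissive = permissive)
}

#' Write longitudinal trial data to CSV
#'
#' Inverse of [read_trial_csv()]: missing outcomes become empty cells and a
#' never-treated exact day is written as \code{"never"}.
#'
#' @param dataset a [trial_data] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_data"))
  df <- data.frame(id = dataset$id, R = dataset$R, D = dataset$D)
  if (!is.null(dataset$T_days))
    df$T_days <- ifelse(is.infinite(dataset$T_days), "never",
                        sprintf("%.17g", dataset$T_days))
  # %.17g round-trips doubles exactly, so write-then-read is bit-faithful
  Y <- apply(dataset$Y, 2L, function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  colnames(Y) <- paste0("y", seq_len(dataset$m))
  utils::write.csv(cbind(df, Y), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}
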