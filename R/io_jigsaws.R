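# Reading/writing JIGSAWS-style kinematics and trial metadata.

EXERCISES <- c("suturing", "knot_tying", "needle_passing")

# canonical exercise token <-> file-name token ("Suturing", "Knot_Tying", ...)
exercise_file_token <- function(exercise) {
  map <- c(suturing = "Suturing", knot_tying = "Knot_Tying",
           needle_passing = "Needle_Passing")
  out <- map[exercise]
  if (anyNA(out)) stopf("unknown exercise: %s",
                        paste(exercise[is.na(out)], collapse = ", "))
  unname(out)
}

exercise_from_token <- function(token) {
  key <- tolower(token)
  if (!all(key %in% EXERCISES))
    stopf("unknown exercise token: %s",
          paste(unique(token[!key %in% EXERCISES]), collapse = ", "))
  key
}

#' Read a JIGSAWS-style kinematics file
#'
#' Parses a plain-text trial recording: one frame per line, 76
#' whitespace-separated finite floats (19 channels for each of the four
#' manipulators), and extracts the Cartesian tool-tip positions according to
#' the column layout. Empty and all-whitespace lines are ignored; an empty
#' file yields a valid 0-frame stream with a warning.
#'
#' @param path path to the kinematics file.
#' @param layout a [jigsaws_layout()] describing the column order.
#' @param sample_rate_hz sampling rate of the recording (default 30 Hz).
#' @return a [kinematic_stream()] with all four manipulators.
#' @export
read_kinematics <- function(path, layout = jigsaws_layout(),
                            sample_rate_hz = 30) {
  if (!file.exists(path)) stopf("kinematics file not found: %s", path)
  stopifnot(inherits(layout, "jigsaws_layout"))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  empty <- matrix(numeric(0), ncol = 3)
  if (!length(keep)) {
    warnf("empty kinematics file: %s (0 samples)", path)
    pos <- stats::setNames(
      rep(list(empty), 4), layout$manipulator_order)
    return(kinematic_stream(pos, sample_rate_hz))
  }
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lens <- lengths(toks)
  bad <- which(lens != layout$n_columns)
  if (length(bad))
    stopf("%s: line %d: expected %d columns, found %d",
          path, keep[bad[1]], layout$n_columns, lens[bad[1]])
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    row <- ceiling(which(is.na(vals))[1] / layout$n_columns)
    stopf("%s: line %d: non-numeric value", path, keep[row])
  }
  if (any(!is.finite(vals))) {
    row <- ceiling(which(!is.finite(vals))[1] / layout$n_columns)
    stopf("%s: line %d: non-finite value", path, keep[row])
  }
  mat <- matrix(vals, ncol = layout$n_columns, byrow = TRUE)
  pos <- lapply(layout$manipulator_order, function(m)
    mat[, layout_position_cols(layout, m), drop = FALSE])
  names(pos) <- layout$manipulator_order
  kinematic_stream(pos, sample_rate_hz)
}

#' Map a participant letter to the self-declared skill level
#'
#' The eight participants are labelled B--I. Four are novices (B, G, H, I),
#' two intermediates (C, F) and two experts (D, E), self-classified by hours
#' of robotic operating experience.
#'
#' @param participant character vector of single letters in B..I.
#' @return character vector of skill levels.
#' @export
participant_skill <- function(participant) {
  map <- c(B = "novice", G = "novice", H = "novice", I = "novice",
           C = "intermediate", F = "intermediate",
           D = "expert", E = "expert")
  out <- map[as.character(participant)]
  if (anyNA(out))
    stopf("unknown participant: %s",
          paste(participant[is.na(out)], collapse = ", "))
  unname(out)
}

#' Classify skill level from hours of robotic experience
#'
#' Fewer than 10 hours is novice, 10 to 100 hours (boundaries inclusive) is
#' intermediate, more than 100 hours is expert.
#'
#' @param hours non-negative numeric vector of hours of experience.
#' @return character vector of skill levels.
#' @export
skill_from_hours <- function(hours) {
  assert_finite_numeric(hours, "hours")
  if (any(hours < 0)) stopf("hours must be non-negative")
  ifelse(hours < 10, "novice", ifelse(hours <= 100, "intermediate", "expert"))
}

# split a GRS total in 6..30 into six items each in 1..5
grs_items_from_total <- function(total) {
  if (total < 6 || total > 30) stopf("GRS total %s outside 6..30", total)
  q <- total %/% 6L
  r <- total %% 6L
  items <- rep(q, 6L) + as.integer(seq_len(6L) <= r)
  if (q == 5L) items <- rep(5L, 6L)  # total == 30
  items
}

#' Read a trial metadata file
#'
#' One line per trial:
#' `<Exercise>_<P>00<r>  <skill letter N/I/E>  <GRS total>  [six GRS items]`
#' where `P` is the participant letter and `r` the repetition (1--5). The
#' six GRS items (respect for tissue, suture/needle handling, time and
#' motion, flow of operation, overall performance, final product quality)
#' are each scored 1--5; when present the total must equal their sum. The
#' skill letter is cross-checked against [participant_skill()]; any mismatch
#' is an error.
#'
#' @param path path to the metadata file.
#' @return a data frame of class `trial_records` with columns `exercise`,
#'   `participant`, `repetition`, `skill_level`, `grs_total` and
#'   `grs_1`..`grs_6` (NA when items are absent).
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  skill_map <- c(N = "novice", I = "intermediate", E = "expert")
  recs <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3)
      stopf("%s: line %d: expected at least 3 fields", path, i)
    m <- regmatches(tok[1], regexec("^([A-Za-z_]+)_([A-Z])00([0-9])$", tok[1]))[[1]]
    if (!length(m))
      stopf("%s: line %d: malformed trial id '%s'", path, i, tok[1])
    exercise <- exercise_from_token(m[2])
    participant <- m[3]
    repetition <- as.integer(m[4])
    if (repetition < 1 || repetition > 5)
      stopf("%s: line %d: repetition %d outside 1..5", path, i, repetition)
    expected <- participant_skill(participant)
    skill <- skill_map[tok[2]]
    if (is.na(skill))
      stopf("%s: line %d: unknown skill letter '%s'", path, i, tok[2])
    if (skill != expected)
      stopf("%s: line %d: skill letter '%s' conflicts with participant %s (%s)",
            path, i, tok[2], participant, expected)
    total <- suppressWarnings(as.integer(tok[3]))
    if (is.na(total) || total < 6 || total > 30)
      stopf("%s: line %d: GRS total '%s' outside 6..30", path, i, tok[3])
    items <- rep(NA_integer_, 6)
    if (length(tok) >= 9) {
      items <- suppressWarnings(as.integer(tok[4:9]))
      if (anyNA(items) || any(items < 1 | items > 5))
        stopf("%s: line %d: GRS items must be integers in 1..5", path, i)
      if (sum(items) != total)
        stopf("%s: line %d: GRS total %d != sum of items %d",
              path, i, total, sum(items))
    }
    data.frame(exercise = exercise, participant = participant,
               repetition = repetition, skill_level = unname(skill),
               grs_total = total,
               grs_1 = items[1], grs_2 = items[2], grs_3 = items[3],
               grs_4 = items[4], grs_5 = items[5], grs_6 = items[6],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(exercise = character(), participant = character(),
                      repetition = integer(), skill_level = character(),
                      grs_total = integer(), grs_1 = integer(),
                      grs_2 = integer(), grs_3 = integer(), grs_4 = integer(),
                      grs_5 = integer(), grs_6 = integer(),
                      stringsAsFactors = FALSE)
  class(out) <- c("trial_records", class(out))
  out
}

#' Write a stream (plus trial identity) to the interchange format
#'
#' The interchange format is a self-describing CSV: `#`-prefixed header
#' lines carry the sample rate, manipulator set and trial identity, followed
#' by a `t,x_<manip>,y_<manip>,z_<manip>,...` table with positions printed
#' at full double precision, so [read_interchange()] round-trips losslessly.
#'
#' @param stream a [kinematic_stream()].
#' @param path output file path.
#' @param trial optional one-row data frame (or list) with `exercise`,
#'   `participant`, `repetition`, `skill_level`, `grs_total`.
#' @return `path`, invisibly.
#' @export
write_interchange <- function(stream, path, trial = NULL) {
  stopifnot(inherits(stream, "kinematic_stream"))
  manips <- names(stream$positions)
  hdr <- c(
    "# surgkin interchange v1",
    sprintf("# sample_rate_hz: %s", fmt_full(stream$sample_rate_hz)),
    sprintf("# manipulators: %s", paste(manips, collapse = " "))
  )
  if (!is.null(trial)) {
    hdr <- c(hdr,
      sprintf("# exercise: %s", trial$exercise),
      sprintf("# participant: %s", trial$participant),
      sprintf("# repetition: %s", trial$repetition),
      sprintf("# skill_level: %s", trial$skill_level),
      sprintf("# grs_total: %s", trial$grs_total))
  }
  cols <- unlist(lapply(manips, function(m) paste(c("x", "y", "z"), m, sep = "_")))
  n <- n_samples(stream)
  body <- character(0)
  if (n > 0) {
    mat <- do.call(cbind, stream$positions)
    t <- (seq_len(n) - 1) / stream$sample_rate_hz
    txt <- matrix(fmt_full(mat), nrow = n)
    body <- do.call(paste, c(list(fmt_full(t)), asplit(txt, 2), sep = ","))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, paste(c("t", cols), collapse = ","), body), con)
  invisible(path)
}

#' Read an interchange file written by [write_interchange()]
#'
#' @param path path to the interchange CSV.
#' @return a list with elements `stream` (a [kinematic_stream()]) and
#'   `trial` (a one-row data frame, or `NULL` when no identity was stored).
#' @export
read_interchange <- function(path) {
  if (!file.exists(path)) stopf("interchange file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get_hdr <- function(key) {
    pat <- paste0("^# ", key, ": ")
    hit <- hdr[grepl(pat, hdr)]
    if (!length(hit)) return(NULL)
    sub(pat, "", hit[1])
  }
  rate <- as.numeric(get_hdr("sample_rate_hz") %||%
                       stopf("%s: missing sample_rate_hz header", path))
  manips <- strsplit(get_hdr("manipulators") %||%
                       stopf("%s: missing manipulators header", path), " ")[[1]]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (!length(body)) stopf("%s: missing column header row", path)
  body <- body[-1]  # column names row
  if (length(body)) {
    vals <- strsplit(body, ",", fixed = TRUE)
    mat <- matrix(as.numeric(unlist(vals)), nrow = length(body), byrow = TRUE)
    pos <- lapply(seq_along(manips), function(i)
      mat[, 1 + (i - 1) * 3 + 1:3, drop = FALSE])
  } else {
    pos <- rep(list(matrix(numeric(0), ncol = 3)), length(manips))
  }
  names(pos) <- manips
  trial <- NULL
  if (!is.null(get_hdr("exercise"))) {
    trial <- data.frame(
      exercise = get_hdr("exercise"),
      participant = get_hdr("participant"),
      repetition = as.integer(get_hdr("repetition")),
      skill_level = get_hdr("skill_level"),
      grs_total = as.integer(get_hdr("grs_total")),
      stringsAsFactors = FALSE)
  }
  list(stream = kinematic_stream(pos, rate), trial = trial)
}

#' Write a stream as a JIGSAWS-style 76-column kinematics file
#'
#' Masters are written from the stream; slave blocks are taken from the
#' stream when present, otherwise mirrored from the corresponding master
#' scaled by `slave_scale` (teleoperation motion scaling). Channels the
#' package does not model are filled with valid placeholders: identity
#' rotation matrices, finite-difference linear velocities, zero angular
#' velocities and a constant gripper angle.
#'
#' @param stream a [kinematic_stream()] holding at least the two masters.
#' @param path output path.
#' @param layout a [jigsaws_layout()].
#' @param slave_scale master-to-slave motion scale factor (default 1).
#' @return `path`, invisibly.
#' @export
write_jigsaws <- function(stream, path, layout = jigsaws_layout(),
                          slave_scale = 1) {
  stopifnot(inherits(stream, "kinematic_stream"))
  n <- n_samples(stream)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  get_pos <- function(m) {
    if (!is.null(stream$positions[[m]])) return(stream$positions[[m]])
    master <- sub("^slave", "master", m)
    if (!is.null(stream$positions[[master]]))
      return(stream$positions[[master]] * slave_scale)
    matrix(0, nrow = n, ncol = 3)
  }
  blocks <- lapply(layout$manipulator_order, function(m) {
    p <- get_pos(m)
    vel <- rbind(rep(0, 3), diff(p) * stream$sample_rate_hz)
    rot <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), nrow = n)
    ang <- matrix(0, nrow = n, ncol = 3)
    grip <- matrix(0.5, nrow = n, ncol = 1)
    cbind(p, rot, vel, ang, grip)
  })
  mat <- do.call(cbind, blocks)
  txt <- matrix(sprintf("%.10g", mat), nrow = n)
  writeLines(apply(txt, 1, paste, collapse = " "), path)
  invisible(path)
}
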