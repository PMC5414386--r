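#' Default emotion valence map
#'
#' The 16-emotion instrument codes each emotion as positive or negative:
#' 6 positive (joy, enjoyment, interest, hope, enthusiasm, curiosity) and
#' 10 negative (sadness, anger, fear, overwhelmed, boredom, distress,
#' overload, confusion, dissonance, ignorance).
#'
#' @return A named character vector mapping emotion label to
#'   `"positive"` or `"negative"`.
#' @export
#' @examples
#' emotion_valences()[["curiosity"]]
emotion_valences <- function() {
  c(
    joy = "positive", enjoyment = "positive", interest = "positive",
    hope = "positive", enthusiasm = "positive", curiosity = "positive",
    sadness = "negative", anger = "negative", fear = "negative",
    overwhelmed = "negative", boredom = "negative", distress = "negative",
    overload = "negative", confusion = "negative", dissonance = "negative",
    ignorance = "negative"
  )
}

#' Valence of an emotion label
#'
#' @param emotion Emotion label (character scalar).
#' @param valence_map Named character vector mapping labels to
#'   `"positive"`/`"negative"`; defaults to [emotion_valences()].
#' @return `"positive"` or `"negative"`.
#' @export
#' @examples
#' valence_of("curiosity")
#' valence_of("dissonance")
valence_of <- function(emotion, valence_map = emotion_valences()) {
  stopifnot(is.character(emotion), length(emotion) == 1L)
  if (!emotion %in% names(valence_map)) {
    stop("unknown emotion '", emotion, "': not in the valence map", call. = FALSE)
  }
  v <- unname(valence_map[[emotion]])
  if (!v %in% c("positive", "negative")) {
    stop("valence for '", emotion, "' must be 'positive' or 'negative'", call. = FALSE)
  }
  v
}

#' Default file schema
#'
#' Long-format CSV layout: one row per (participant, occasion), one column
#' per emotion plus the two complexity items. The schema maps logical roles
#' to column names and carries the valence map.
#'
#' @param valence_map Named character vector of emotion valences.
#' @return A list with elements `participant`, `occasion`, `conceptual`,
#'   `performative` (column names) and `valence` (the map).
#' @export
default_schema <- function(valence_map = emotion_valences()) {
  list(
    participant = "participant",
    occasion = "occasion",
    conceptual = "complexity_conceptual",
    performative = "complexity_performative",
    valence = as.list(valence_map)
  )
}

#' Read or write a schema as YAML
#'
#' @param path File path.
#' @return `load_schema()` returns the schema list; `write_schema()`
#'   returns `path` invisibly.
#' @export
load_schema <- function(path) {
  s <- yaml::read_yaml(path)
  req <- c("participant", "occasion", "conceptual", "performative", "valence")
  missing <- setdiff(req, names(s))
  if (length(missing)) {
    stop("schema is missing fields: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  s
}

#' @rdname load_schema
#' @param schema A schema list as returned by [default_schema()].
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(schema, path)
  invisible(path)
}

check_likert <- function(x, what, rows) {
  bad <- !is.finite(x) | x != round(x) | x < 1 | x > 5
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(
      what, " at row ", rows[i], " is ", x[i],
      ": scores must be integers in 1..5", call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Construct a ratings dataset
#'
#' Bundles per-(participant, emotion, occasion) intensity ratings with the
#' two per-(participant, occasion) complexity items and the valence map.
#' All participants must be complete cases: every rating and complexity
#' cell present at every occasion, all values integers in 1..5.
#'
#' @param ratings Tibble/data frame with columns `participant`, `emotion`,
#'   `occasion`, `score`.
#' @param complexity Tibble/data frame with columns `participant`,
#'   `occasion`, `conceptual`, `performative`.
#' @param valence_map Named character vector of emotion valences covering
#'   every emotion in `ratings`.
#' @return An object of class `ratings_dataset`: a list with tibbles
#'   `ratings` (with a `valence` column attached) and `complexity`, plus
#'   `participants`, `emotions` (the valence map restricted to the data)
#'   and `n_occasions`.
#' @export
ratings_dataset <- function(ratings, complexity, valence_map = emotion_valences()) {
  ratings <- tibble::as_tibble(ratings)
  complexity <- tibble::as_tibble(complexity)
  stopifnot(all(c("participant", "emotion", "occasion", "score") %in% names(ratings)))
  stopifnot(all(c("participant", "occasion", "conceptual", "performative") %in% names(complexity)))

  ratings$participant <- as.character(ratings$participant)
  complexity$participant <- as.character(complexity$participant)

  emotions <- unique(ratings$emotion)
  unknown <- setdiff(emotions, names(valence_map))
  if (length(unknown)) {
    stop("emotions without a valence entry: ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  occasions <- sort(unique(ratings$occasion))
  if (!identical(as.integer(occasions), seq_len(length(occasions)))) {
    stop("occasions must be the consecutive integers 1..T", call. = FALSE)
  }
  n_occ <- length(occasions)
  if (n_occ < 4L) {
    stop("at least 4 occasions are required to test slope changes", call. = FALSE)
  }

  check_likert(ratings$score, "rating", seq_len(nrow(ratings)))
  check_likert(complexity$conceptual, "conceptual complexity", seq_len(nrow(complexity)))
  check_likert(complexity$performative, "performative complexity", seq_len(nrow(complexity)))

  participants <- unique(ratings$participant)

  # completeness: every (participant, emotion, occasion) and complexity cell
  key <- paste(ratings$participant, ratings$emotion, ratings$occasion)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, emotion, occasion) cell: ", key[anyDuplicated(key)], call. = FALSE)
  }
  expected <- length(participants) * length(emotions) * n_occ
  if (nrow(ratings) != expected) {
    stop("incomplete ratings: expected ", expected, " cells, found ", nrow(ratings), call. = FALSE)
  }
  ckey <- paste(complexity$participant, complexity$occasion)
  if (anyDuplicated(ckey)) {
    stop("duplicate (participant, occasion) complexity cell", call. = FALSE)
  }
  if (nrow(complexity) != length(participants) * n_occ ||
      !setequal(complexity$participant, participants)) {
    stop("complexity cells do not cover every participant x occasion", call. = FALSE)
  }

  ratings$valence <- unname(valence_map[ratings$emotion])
  ratings <- dplyr::arrange(ratings, .data$participant, .data$emotion, .data$occasion)
  complexity <- dplyr::arrange(complexity, .data$participant, .data$occasion)

  structure(
    list(
      ratings = ratings,
      complexity = complexity,
      participants = participants,
      emotions = valence_map[emotions],
      n_occasions = n_occ
    ),
    class = "ratings_dataset"
  )
}

#' @export
print.ratings_dataset <- function(x, ...) {
  n_pos <- sum(x$emotions == "positive")
  cat(
    "<ratings_dataset> ", length(x$participants), " participants x ",
    length(x$emotions), " emotions (", n_pos, " positive, ",
    length(x$emotions) - n_pos, " negative) x ", x$n_occasions,
    " occasions\n",
    sep = ""
  )
  invisible(x)
}

#' Number of trajectories in a dataset
#'
#' @param dataset A `ratings_dataset`.
#' @return Named integer vector: total, positive, negative.
#' @export
n_trajectories <- function(dataset) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  p <- length(dataset$participants)
  c(
    total = p * length(dataset$emotions),
    positive = p * sum(dataset$emotions == "positive"),
    negative = p * sum(dataset$emotions == "negative")
  )
}

#' Load a ratings cohort from a long-format CSV
#'
#' Expects one row per (participant, occasion) with one column per emotion
#' and the two complexity items. Participants with any missing cell are
#' dropped with a warning (complete-case rule); out-of-range or
#' non-integer scores and duplicate (participant, occasion) rows are hard
#' errors.
#'
#' @param path CSV file path (UTF-8, comma-delimited, header row).
#' @param schema Schema list, see [default_schema()].
#' @return A [ratings_dataset()].
#' @export
load_ratings <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  valence_map <- unlist(schema$valence)
  emotions <- names(valence_map)
  need <- c(schema$participant, schema$occasion, schema$conceptual,
            schema$performative, emotions)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("input lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  pid <- as.character(df[[schema$participant]])
  occ <- df[[schema$occasion]]
  if (anyDuplicated(paste(pid, occ))) {
    i <- which(duplicated(paste(pid, occ)))[1L]
    stop("duplicate (participant, occasion) row: ", pid[i], ", ", occ[i], call. = FALSE)
  }

  value_cols <- c(emotions, schema$conceptual, schema$performative)
  occasions <- sort(unique(occ))
  T_n <- length(occasions)

  # complete-case rule: a participant must have every occasion and no NA cell
  keep <- vapply(unique(pid), function(p) {
    rows <- df[pid == p, value_cols, drop = FALSE]
    nrow(rows) == T_n && !anyNA(rows) &&
      setequal(occ[pid == p], occasions)
  }, logical(1))
  dropped <- unique(pid)[!keep]
  if (length(dropped)) {
    warning(
      "dropping incomplete participant(s): ", paste(dropped, collapse = ", "),
      call. = FALSE
    )
    sel <- pid %in% unique(pid)[keep]
    df <- df[sel, , drop = FALSE]
    pid <- pid[sel]
    occ <- occ[sel]
  }
  if (nrow(df) == 0L) stop("no complete participants in ", path, call. = FALSE)

  # validate scores with file row numbers (header = row 1)
  file_row <- as.integer(rownames(df)) + 1L
  for (col in value_cols) check_likert(df[[col]], paste0("column '", col, "'"), file_row)

  long <- tibble::tibble(
    participant = rep(pid, times = length(emotions)),
    emotion = rep(emotions, each = nrow(df)),
    occasion = rep(as.integer(occ), times = length(emotions)),
    score = as.integer(unlist(df[emotions], use.names = FALSE))
  )
  complexity <- tibble::tibble(
    participant = pid,
    occasion = as.integer(occ),
    conceptual = as.integer(df[[schema$conceptual]]),
    performative = as.integer(df[[schema$performative]])
  )
  ratings_dataset(long, complexity, valence_map)
}

#' Write a ratings cohort to a long-format CSV
#'
#' Inverse of [load_ratings()]: one row per (participant, occasion),
#' emotion and complexity-item columns named by the schema.
#'
#' @param dataset A `ratings_dataset`.
#' @param path Output CSV path.
#' @param schema Schema list naming the columns.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(dataset, path, schema = default_schema()) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  emotions <- names(dataset$emotions)
  base <- dataset$complexity
  wide <- data.frame(
    participant = base$participant,
    occasion = base$occasion,
    check.names = FALSE
  )
  names(wide) <- c(schema$participant, schema$occasion)
  key <- paste(base$participant, base$occasion)
  for (e in emotions) {
    sub <- dataset$ratings[dataset$ratings$emotion == e, ]
    wide[[e]] <- sub$score[match(key, paste(sub$participant, sub$occasion))]
  }
  wide[[schema$conceptual]] <- base$conceptual
  wide[[schema$performative]] <- base$performative
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one emotion trajectory
#'
#' @param dataset A `ratings_dataset`.
#' @param participant Participant identifier.
#' @param emotion Emotion label.
#' @return An `emotion_trajectory`: list with `participant`, `emotion`,
#'   `valence`, `occasions` (1..T) and `scores`.
#' @export
extract_trajectory <- function(dataset, participant, emotion) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  participant <- as.character(participant)
  if (!participant %in% dataset$participants) {
    stop("unknown participant: ", participant, call. = FALSE)
  }
  if (!emotion %in% names(dataset$emotions)) {
    stop("unknown emotion: ", emotion, call. = FALSE)
  }
  sub <- dataset$ratings[
    dataset$ratings$participant == participant & dataset$ratings$emotion == emotion,
  ]
  sub <- sub[order(sub$occasion), ]
  emotion_trajectory(
    scores = sub$score,
    participant = participant,
    emotion = emotion,
    valence = unname(dataset$emotions[[emotion]])
  )
}

#' Construct an emotion trajectory
#'
#' @param scores Integer vector of Likert scores in 1..5, ordered by
#'   occasion; length at least 4.
#' @param participant,emotion Identifiers (optional for ad hoc series).
#' @param valence `"positive"` or `"negative"`.
#' @return An `emotion_trajectory` object.
#' @export
emotion_trajectory <- function(scores, participant = NA_character_,
                               emotion = NA_character_, valence = NA_character_) {
  scores <- as.numeric(scores)
  if (length(scores) < 4L) {
    stop("a trajectory needs at least 4 occasions", call. = FALSE)
  }
  structure(
    list(
      participant = participant, emotion = emotion, valence = valence,
      occasions = seq_along(scores), scores = scores
    ),
    class = "emotion_trajectory"
  )
}

#' @export
print.emotion_trajectory <- function(x, ...) {
  cat(
    "<emotion_trajectory> ", x$participant, " / ", x$emotion,
    " (", x$valence, "): ", paste(x$scores, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' All trajectories of a dataset
#'
#' @param dataset A `ratings_dataset`.
#' @return A list of `emotion_trajectory` objects, ordered by participant
#'   then emotion (the order of the valence map).
#' @export
trajectories <- function(dataset) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  out <- vector("list", length(dataset$participants) * length(dataset$emotions))
  i <- 0L
  for (p in dataset$participants) {
    for (e in names(dataset$emotions)) {
      i <- i + 1L
      out[[i]] <- extract_trajectory(dataset, p, e)
    }
  }
  out
}

#' Per-occasion perceived-complexity series for one participant
#'
#' The complexity score at each occasion is the arithmetic mean of the
#' conceptual and performative items, so values lie on the half-integer
#' grid 1, 1.5, ..., 5.
#'
#' @param dataset A `ratings_dataset`.
#' @param participant Participant identifier.
#' @return A `complexity_series`: list with `participant`, `occasions`,
#'   `values`.
#' @export
complexity_series <- function(dataset, participant) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  participant <- as.character(participant)
  if (!participant %in% dataset$participants) {
    stop("unknown participant: ", participant, call. = FALSE)
  }
  sub <- dataset$complexity[dataset$complexity$participant == participant, ]
  sub <- sub[order(sub$occasion), ]
  structure(
    list(
      participant = participant,
      occasions = sub$occasion,
      values = (sub$conceptual + sub$performative) / 2
    ),
    class = "complexity_series"
  )
}

# participants x occasions matrix of per-occasion complexity means
complexity_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "ratings_dataset"))
  p <- dataset$participants
  m <- matrix(
    NA_real_, nrow = length(p), ncol = dataset$n_occasions,
    dimnames = list(p, seq_len(dataset$n_occasions))
  )
  cx <- dataset$complexity
  m[cbind(match(cx$participant, p), cx$occasion)] <-
    (cx$conceptual + cx$performative) / 2
  m
}
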