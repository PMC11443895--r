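#' Generations elapsed per day under a serial-passage bottleneck
#'
#' A daily transfer of a fraction `b` of the culture, regrown to the same
#' density, corresponds to `log2(1/b)` doublings: a 1% bottleneck gives
#' 6.64 generations per day.
#'
#' @param bottleneck Fraction transferred daily, in (0, 1).
#' @return Generations per day (real).
#' @examples
#' generations_per_day(0.01)  # 6.6439
#' @export
generations_per_day <- function(bottleneck) {
  if (any(bottleneck <= 0) || any(bottleneck >= 1)) {
    stop("bottleneck must lie strictly between 0 and 1")
  }
  log2(1 / bottleneck)
}

#' Serial-passage scheme
#'
#' @param bottleneck Daily transfer fraction (default 0.01, i.e. 1:100).
#' @param days Number of passages.
#' @return List of class `"passage_scheme"`.
#' @export
passage_scheme <- function(bottleneck = 0.01, days = 7) {
  stopifnot(days >= 1)
  generations_per_day(bottleneck)  # validates the fraction
  structure(list(bottleneck = bottleneck, days = as.integer(days)),
            class = "passage_scheme")
}

#' Cumulative generations over a passage scheme
#'
#' @param scheme A [passage_scheme()], or a bottleneck fraction if `days`
#'   is given.
#' @param days Number of days (when `scheme` is a fraction).
#' @return `days * log2(1/bottleneck)`; 0 for zero days.
#' @examples
#' cumulative_generations(passage_scheme(0.01, 7))  # 46.51
#' @export
cumulative_generations <- function(scheme, days = NULL) {
  if (inherits(scheme, "passage_scheme")) {
    scheme$days * generations_per_day(scheme$bottleneck)
  } else {
    if (is.null(days)) stop("days required when scheme is a fraction")
    if (days == 0) return(0)
    days * generations_per_day(scheme)
  }
}

#' Collection of evolution lines with daily dynamic-range trajectories
#'
#' @param dr Numeric matrix, days x lines, of daily dynamic ranges (> 0).
#' @param meta data.frame with one row per line: `line_id`, `medium`
#'   (`"-IPTG"`/`"+IPTG"`), `copy_class` (`"medium"`/`"high"`).
#' @param scheme A [passage_scheme()] shared by all lines.
#' @return Object of class `"evolution_lines"`.
#' @export
evolution_lines <- function(dr, meta, scheme) {
  stopifnot(is.matrix(dr), all(dr > 0), inherits(scheme, "passage_scheme"),
            nrow(dr) == scheme$days, ncol(dr) == nrow(meta),
            all(c("line_id", "medium", "copy_class") %in% names(meta)))
  colnames(dr) <- meta$line_id
  rownames(dr) <- paste0("day", seq_len(nrow(dr)))
  structure(list(dr = dr, meta = meta, scheme = scheme),
            class = "evolution_lines")
}

#' Simulate serial-passage evolution of the regulator circuit
#'
#' Per line and genetic element (reporter gene, regulator promoter), the day
#' a loss-of-function mutation arises is geometric with the element's daily
#' probability; after a takeover lag (the sweep of the mutant through the
#' bottlenecked population, >= 1 day) the line's dynamic range drops from
#' `dr_functional` to `dr_lost`. The first event across elements determines
#' the trajectory.
#'
#' @param n_lines Lines per arm.
#' @param days Days of passaging.
#' @param bottleneck Daily transfer fraction.
#' @param mutation_prob Named numeric vector, per-day loss probability per
#'   element, e.g. `c(reporter = 0.2, promoter = 0.05)`.
#' @param dr_functional Dynamic range while the circuit is intact.
#' @param dr_lost Dynamic range after loss (default 1, no regulation).
#' @param lag Takeover lag in days (>= 1).
#' @param noise_sdlog Log-normal measurement noise on daily dynamic ranges
#'   (0 = none).
#' @param medium,copy_class Arm labels stored in the metadata.
#' @param seed Integer seed.
#' @return List with `lines` (an [evolution_lines()]) and `truth`
#'   (data.frame `line_id`, `day`, `element` of mutation events; zero rows
#'   when none).
#' @export
gen_evolution <- function(n_lines = 5, days = 7, bottleneck = 0.01,
                          mutation_prob = c(reporter = 0.2, promoter = 0.05),
                          dr_functional = 10, dr_lost = 1, lag = 1,
                          noise_sdlog = 0, medium = "-IPTG",
                          copy_class = "medium", seed = 1) {
  stopifnot(dr_functional > 0, dr_lost > 0, lag >= 1,
            all(mutation_prob >= 0), all(mutation_prob <= 1))
  generations_per_day(bottleneck)
  set.seed(seed)
  scheme <- passage_scheme(bottleneck, days)
  ids <- sprintf("line%02d", seq_len(n_lines))
  dr <- matrix(dr_functional, nrow = days, ncol = n_lines)
  events <- list()
  for (l in seq_len(n_lines)) {
    first_day <- Inf
    first_el <- NA_character_
    for (el in names(mutation_prob)) {
      p <- mutation_prob[[el]]
      if (p == 0) next
      d <- if (p == 1) 1L else rgeom(1, p) + 1L
      if (d < first_day) { first_day <- d; first_el <- el }
    }
    if (is.finite(first_day) && first_day <= days) {
      events[[length(events) + 1]] <- data.frame(
        line_id = ids[l], day = as.integer(first_day), element = first_el,
        stringsAsFactors = FALSE)
      lost_from <- first_day + lag
      if (lost_from <= days) dr[lost_from:days, l] <- dr_lost
    }
  }
  if (noise_sdlog > 0) {
    dr <- dr * matrix(rlnorm(length(dr), 0, noise_sdlog), nrow = days)
  }
  meta <- data.frame(line_id = ids, medium = medium, copy_class = copy_class,
                     stringsAsFactors = FALSE)
  truth <- if (length(events)) {
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  } else {
    data.frame(line_id = character(), day = integer(), element = character(),
               stringsAsFactors = FALSE)
  }
  list(lines = evolution_lines(dr, meta, scheme), truth = truth)
}

#' Detect loss of regulatory function in one trajectory
#'
#' The loss day is the first (1-based) day at which the dynamic range falls
#' below `threshold` and stays below it for `persistence` consecutive days;
#' it is reported together with the corresponding cumulative generations.
#'
#' @param trajectory Numeric vector of daily dynamic ranges (or a column of
#'   an [evolution_lines()] matrix).
#' @param threshold Dynamic-range threshold (> 1).
#' @param persistence Consecutive days required below threshold (>= 1).
#' @param bottleneck Daily transfer fraction (for the generations
#'   conversion).
#' @return List with `day` and `generations`, or `NULL` when never
#'   triggered. A trajectory shorter than the persistence window returns
#'   `NULL` with a warning.
#' @examples
#' detect_loss(c(10, 10, 10, 1.2, 1.1, 1, 1), threshold = 2)
#' @export
detect_loss <- function(trajectory, threshold = 2, persistence = 2,
                        bottleneck = 0.01) {
  stopifnot(threshold > 1, persistence >= 1)
  if (length(trajectory) < persistence) {
    warning("trajectory shorter than the persistence window")
    return(NULL)
  }
  below <- trajectory < threshold
  for (d in seq_len(length(trajectory) - persistence + 1)) {
    if (all(below[d:(d + persistence - 1)])) {
      return(list(day = d,
                  generations = d * generations_per_day(bottleneck)))
    }
  }
  NULL
}

#' Summarize evolution lines: heatmap matrix and per-arm survival
#'
#' @param lines An [evolution_lines()] collection.
#' @param threshold,persistence Loss criterion, see [detect_loss()].
#' @return List with `heatmap` (days x lines dynamic-range matrix) and
#'   `arms` (data.frame per medium x copy class: `n_lines`,
#'   `median_loss_generation` (`NA` when no line lost), `surviving_fraction`
#'   of lines never triggering the loss criterion).
#' @export
summarize_lines <- function(lines, threshold = 2, persistence = 2) {
  stopifnot(inherits(lines, "evolution_lines"))
  b <- lines$scheme$bottleneck
  loss <- lapply(seq_len(ncol(lines$dr)), function(j) {
    detect_loss(lines$dr[, j], threshold, persistence, b)
  })
  gens <- vapply(loss, function(e) if (is.null(e)) NA_real_ else
    e$generations, 0)
  arm <- interaction(lines$meta$medium, lines$meta$copy_class, drop = TRUE)
  rows <- lapply(levels(arm), function(a) {
    sel <- arm == a
    data.frame(
      medium = lines$meta$medium[sel][1],
      copy_class = lines$meta$copy_class[sel][1],
      n_lines = sum(sel),
      median_loss_generation = if (all(is.na(gens[sel]))) NA_real_ else
        median(gens[sel], na.rm = TRUE),
      surviving_fraction = mean(is.na(gens[sel])),
      stringsAsFactors = FALSE)
  })
  list(heatmap = lines$dr,
       arms = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write / read evolution trajectories as long-format TSV
#'
#' Columns `line`, `day`, `dr`.
#'
#' @param lines An [evolution_lines()].
#' @param path File path.
#' @param bottleneck Bottleneck to attach on read.
#' @return `path` invisibly (write); an [evolution_lines()] (read, with
#'   `medium`/`copy_class` set to `NA` unless present as extra columns).
#' @export
write_trajectories_tsv <- function(lines, path) {
  long <- data.frame(
    line = rep(colnames(lines$dr), each = nrow(lines$dr)),
    day = rep(seq_len(nrow(lines$dr)), ncol(lines$dr)),
    dr = as.vector(lines$dr),
    medium = rep(lines$meta$medium, each = nrow(lines$dr)),
    copy_class = rep(lines$meta$copy_class, each = nrow(lines$dr)))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_tsv
#' @export
read_trajectories_tsv <- function(path, bottleneck = 0.01) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(long$line)
  days <- max(long$day)
  dr <- matrix(NA_real_, nrow = days, ncol = length(ids))
  for (j in seq_along(ids)) {
    sub <- long[long$line == ids[j], ]
    dr[sub$day, j] <- sub$dr
  }
  meta <- data.frame(
    line_id = ids,
    medium = if ("medium" %in% names(long))
      vapply(ids, function(i) long$medium[long$line == i][1], "") else
        NA_character_,
    copy_class = if ("copy_class" %in% names(long))
      vapply(ids, function(i) long$copy_class[long$line == i][1], "") else
        NA_character_,
    stringsAsFactors = FALSE)
  evolution_lines(dr, meta, passage_scheme(bottleneck, days))
}
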