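#' Canonical upper-body marker schema
#'
#' The analysis pipeline tracks a 14-marker upper-body set: bilateral
#' acromions and elbows, the four pelvic landmarks (anterior and posterior
#' superior iliac spines) and five spinous-process markers (S1, L3, L1, T6,
#' T1) sampled by an optoelectronic system. `marker_schema()` builds the
#' schema object used by all readers: the canonical label set, the subset
#' required for each motor task, and an alias map translating vendor labels
#' (e.g. `"R.Acromion"`) onto canonical ones.
#'
#' @param aliases named character vector mapping vendor labels (names) to
#'   canonical labels (values). Must be injective onto canonical labels.
#' @param extra_optional additional canonical labels to accept (tracked but
#'   unused by the angle set).
#' @return An object of class `marker_schema` with elements `canonical`,
#'   `required` (list per task) and `aliases`.
#' @examples
#' sch <- marker_schema(aliases = c("R.Acromion" = "RACR"))
#' sch$required$twist
#' @export
marker_schema <- function(aliases = character(), extra_optional = character()) {
  canonical <- c(
    "RACR", "LACR", "RELB", "LELB",
    "RASIS", "LASIS", "RPSIS", "LPSIS",
    "S1", "L3", "L1", "T6", "T1"
  )
  canonical <- union(canonical, extra_optional)

  pelvis <- c("RASIS", "LASIS", "RPSIS", "LPSIS")
  spine <- c("S1", "L3", "L1", "T6", "T1")
  required <- list(
    anterior_flexion = c(pelvis, spine),
    lateral_bending  = c(pelvis, "LACR", "RACR"),
    twist            = c(pelvis, "LACR", "RACR"),
    frontal_rise     = c(pelvis, "LACR", "RACR", "LELB", "RELB"),
    lateral_rise     = c(pelvis, "LACR", "RACR", "LELB", "RELB"),
    backward_push    = c(pelvis, "LACR", "RACR", "LELB", "RELB")
  )

  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases))))
      stop("aliases must be a named character vector (vendor -> canonical)")
    if (anyDuplicated(names(aliases)))
      stop("duplicate vendor labels in alias map")
    if (anyDuplicated(aliases))
      stop("alias map must be injective: duplicated canonical targets ",
           paste(unique(aliases[duplicated(aliases)]), collapse = ", "))
    bad <- setdiff(aliases, canonical)
    if (length(bad))
      stop("alias targets are not canonical labels: ", paste(bad, collapse = ", "))
  }

  structure(
    list(canonical = canonical, required = required, aliases = aliases),
    class = "marker_schema"
  )
}

#' @export
print.marker_schema <- function(x, ...) {
  cat("<marker_schema> ", length(x$canonical), " canonical labels, ",
      length(x$aliases), " aliases\n", sep = "")
  invisible(x)
}

#' Map vendor labels onto the canonical schema
#'
#' @param labels character vector of labels as found in a file.
#' @param schema a [marker_schema()].
#' @return character vector: canonical label where recognised (directly or
#'   via alias), `NA` otherwise.
#' @keywords internal
resolve_labels <- function(labels, schema) {
  out <- ifelse(labels %in% schema$canonical, labels, NA_character_)
  if (length(schema$aliases)) {
    hit <- match(labels, names(schema$aliases))
    out[!is.na(hit)] <- schema$aliases[hit[!is.na(hit)]]
  }
  out
}

#' Check that a trajectory set carries every marker a task needs
#'
#' @param t a [marker_trajectory_set()].
#' @param task one of the six motor tasks.
#' @param schema a [marker_schema()].
#' @return invisibly `TRUE`; errors naming the missing markers otherwise.
#' @export
check_required_markers <- function(t, task, schema = marker_schema()) {
  task <- match.arg(task, names(schema$required))
  missing <- setdiff(schema$required[[task]], names(t$positions))
  # either PSIS side satisfies the pelvic-plane requirement
  psis <- c("RPSIS", "LPSIS")
  if (all(psis %in% missing) == FALSE) missing <- setdiff(missing, psis)
  if (length(missing))
    stop("task '", task, "' requires missing marker(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Trial metadata
#'
#' Describes one recorded (or simulated) trial: who performed it, in which
#' study arm and session, which motor task, which side and which of the two
#' sets. The treated group (WG) is assessed at PRE, ACUTE and POST; the
#' control group (CG) only at PRE and POST. Only anterior trunk flexion is
#' side-less.
#'
#' @param participant_id character scalar.
#' @param group `"WG"` or `"CG"`.
#' @param session `"PRE"`, `"ACUTE"` or `"POST"` (`"ACUTE"` valid for WG only).
#' @param task one of `anterior_flexion`, `lateral_bending`, `twist`,
#'   `frontal_rise`, `lateral_rise`, `backward_push`.
#' @param side `"left"`, `"right"` or `"none"` (`"none"` only for
#'   `anterior_flexion`).
#' @param set_index 1 or 2.
#' @return object of class `trial_metadata`.
#' @export
trial_metadata <- function(participant_id, group, session, task,
                           side = "none", set_index = 1L) {
  group <- match.arg(group, c("WG", "CG"))
  session <- match.arg(session, c("PRE", "ACUTE", "POST"))
  task <- match.arg(task, c("anterior_flexion", "lateral_bending", "twist",
                            "frontal_rise", "lateral_rise", "backward_push"))
  side <- match.arg(side, c("left", "right", "none"))
  if (session == "ACUTE" && group == "CG")
    stop("session ACUTE is only defined for group WG")
  if (side == "none" && task != "anterior_flexion")
    stop("side = 'none' is only valid for anterior_flexion")
  if (side != "none" && task == "anterior_flexion")
    stop("anterior_flexion is a side-less task")
  if (!set_index %in% c(1L, 2L)) stop("set_index must be 1 or 2")
  structure(
    list(participant_id = as.character(participant_id), group = group,
         session = session, task = task, side = side,
         set_index = as.integer(set_index)),
    class = "trial_metadata"
  )
}

#' @export
print.trial_metadata <- function(x, ...) {
  cat(sprintf("<trial_metadata> %s %s %s %s side=%s set=%d\n",
              x$participant_id, x$group, x$session, x$task, x$side,
              x$set_index))
  invisible(x)
}
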