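## Session manifests: one participant, three visits (train/validation/test
## in chronological order), paths to the paired LFP + force CSVs, the
## motionless baseline interval used for weight estimation, and native
## sampling rates.

#' Construct a session manifest
#'
#' @param participant_id participant identifier string.
#' @param visits list of visit entries, each a list with fields
#'   `visit_label`, `months_since_IP` (integer months since initial
#'   programming), `lfp_path`, `force_path`, `baseline_interval`
#'   (`c(start_s, end_s)`), `role` (`"train"`, `"validation"` or `"test"`),
#'   and optional `lfp_fs` (default 422), `force_fs` (default 100),
#'   `offset_s` (LFP-vs-force start offset, default 0), `task_interval`
#'   (optional `c(start_cue_s, stop_cue_s)` crop).
#' @return a `"session_manifest"` object (validated).
#' @export
session_manifest <- function(participant_id, visits) {
  m <- structure(list(participant_id = participant_id, visits = visits),
                 class = "session_manifest")
  validate_manifest(m)
  m
}

#' Validate a session manifest
#'
#' Checks: exactly one visit per role; roles assigned in chronological order
#' of `months_since_IP` (train earliest, test latest); baseline intervals
#' well-formed.
#'
#' @param m a `"session_manifest"`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_manifest <- function(m) {
  roles <- vapply(m$visits, `[[`, "", "role")
  months <- vapply(m$visits, function(v) as.numeric(v$months_since_IP), 0)
  need <- c("train", "validation", "test")
  if (any(duplicated(roles))) {
    stop(sprintf("manifest invalid: role '%s' assigned to more than one visit",
                 roles[duplicated(roles)][1]))
  }
  if (!all(roles %in% need)) {
    stop("manifest invalid: roles must be train/validation/test")
  }
  if (!setequal(roles, need)) {
    stop(sprintf("manifest invalid: missing role(s) %s",
                 paste(setdiff(need, roles), collapse = ", ")))
  }
  ord <- order(months)
  if (!identical(roles[ord], need)) {
    stop("manifest invalid: roles not in chronological order (train earliest, test latest)")
  }
  for (v in m$visits) {
    bi <- v$baseline_interval
    if (length(bi) != 2L || bi[1] >= bi[2]) {
      stop(sprintf("manifest invalid: bad baseline_interval in visit '%s'",
                   v$visit_label))
    }
  }
  invisible(m)
}

visit_by_role <- function(m, role) {
  for (v in m$visits) if (identical(v$role, role)) return(v)
  stop(sprintf("no visit with role '%s'", role))
}

#' Read a session manifest from JSON
#' @param path JSON file written by [write_manifest()] (or hand-authored
#'   with the same fields). Relative data paths are resolved against the
#'   manifest's directory.
#' @return a validated `"session_manifest"`.
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  visits <- lapply(raw$visits, function(v) {
    v$baseline_interval <- as.numeric(unlist(v$baseline_interval))
    if (!is.null(v$task_interval)) {
      v$task_interval <- as.numeric(unlist(v$task_interval))
    }
    for (f in c("lfp_path", "force_path")) {
      if (!file.exists(v[[f]]) && file.exists(file.path(base, v[[f]]))) {
        v[[f]] <- file.path(base, v[[f]])
      }
    }
    v
  })
  session_manifest(raw$participant_id, visits)
}

#' Write a session manifest to JSON
#' @param m a `"session_manifest"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> participant %s, %d visits\n",
              x$participant_id, length(x$visits)))
  for (v in x$visits) {
    cat(sprintf("  %-10s %-11s month %3d  lfp=%s force=%s\n", v$visit_label,
                v$role, as.integer(v$months_since_IP), basename(v$lfp_path),
                basename(v$force_path)))
  }
  invisible(x)
}
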