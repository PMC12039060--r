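#' Pipeline configuration
#'
#' Assembles the configuration list used throughout the pipeline. All
#' thresholds default to the method's printed values: a 0.45 Angstrom
#' distance tolerance for bond perception, a +10 eV orbital cutoff under
#' which molecular orbitals are doubly occupied, the -9 eV low-LUMO and
#' -10.2 eV high-HOMO frontier thresholds for the iterative two-electron
#' charge corrections, and a 1.3 distance-ratio cutoff for pruning spurious
#' haptic bonds.
#'
#' @param tolerance bond-perception distance tolerance in Angstrom.
#' @param cutoffEnergy orbital energy cutoff E_C in eV; orbitals below it
#'   are filled with double occupancy.
#' @param lumoLow LUMO threshold in eV: a positive ligand charge with a LUMO
#'   below this gains two electrons, iteratively.
#' @param homoHigh HOMO threshold in eV: a ligand charge of -2 or lower with
#'   a HOMO above this loses two electrons, iteratively.
#' @param hapticRatioCutoff metal-distance ratio above which a perceived
#'   haptic bond is cut relative to the shortest bond of its patch.
#' @param maxAdjust safety cap on two-electron adjustment steps per direction;
#'   a pure runaway guard (large ligands legitimately need several steps).
#' @param resonanceCap maximum number of resonance candidates kept per ligand.
#' @param allowCarbenes whether the carbene-allowed enumeration pass runs.
#' @param maxValence named integer vector of per-element neighbor-count
#'   limits for valence trimming; defaults to \code{elementTables()$maxValence}.
#' @param verbose emit per-event log messages.
#'
#' @return a named list understood by the pipeline functions.
#' @examples
#' cfg <- tmcConfig(tolerance = 0.4)
#' cfg$tolerance
#' @export
tmcConfig <- function(tolerance = 0.45,
                      cutoffEnergy = 10,
                      lumoLow = -9,
                      homoHigh = -10.2,
                      hapticRatioCutoff = 1.3,
                      maxAdjust = 50L,
                      resonanceCap = 500L,
                      allowCarbenes = TRUE,
                      maxValence = NULL,
                      verbose = FALSE) {
  if (is.null(maxValence)) maxValence <- .maxValence
  list(tolerance = tolerance,
       cutoffEnergy = cutoffEnergy,
       lumoLow = lumoLow,
       homoHigh = homoHigh,
       hapticRatioCutoff = hapticRatioCutoff,
       maxAdjust = as.integer(maxAdjust),
       resonanceCap = as.integer(resonanceCap),
       allowCarbenes = isTRUE(allowCarbenes),
       maxValence = maxValence,
       verbose = isTRUE(verbose))
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults. The
#' \code{maxValence} block, when present, overrides individual elements.
#'
#' @param path YAML file path.
#' @return a configuration list as from \code{\link{tmcConfig}}.
#' @export
readTmcConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(tmcConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  mv <- .maxValence
  if (!is.null(raw$maxValence)) {
    ov <- unlist(raw$maxValence)
    mv[names(ov)] <- as.integer(ov)
    raw$maxValence <- NULL
  }
  cfg <- do.call(tmcConfig, raw)
  cfg$maxValence <- mv
  cfg
}

# Structured logging: appends JSONL records when a connection is configured,
# and messages when verbose. Kept deliberately simple; the log is a debugging
# aid, never parsed by the pipeline itself.
.tmcLogEnv <- new.env(parent = emptyenv())

#' Direct structured log output to a JSONL file
#'
#' @param path file to append JSON-lines records to, or NULL to disable.
#' @return invisibly, the previous path.
#' @export
tmcLogTo <- function(path = NULL) {
  old <- .tmcLogEnv$path
  .tmcLogEnv$path <- path
  invisible(old)
}

.tmcLog <- function(event, ..., config = NULL) {
  rec <- c(list(event = event), list(...))
  if (!is.null(.tmcLogEnv$path)) {
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    cat(line, "\n", sep = "", file = .tmcLogEnv$path, append = TRUE)
  }
  if (!is.null(config) && isTRUE(config$verbose)) {
    detail <- paste(names(rec[-1]), unlist(lapply(rec[-1], paste,
                                                  collapse = ",")),
                    sep = "=", collapse = " ")
    message("[tmcSMILES] ", event, " ", detail)
  }
  invisible(NULL)
}
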