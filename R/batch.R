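#' Batch conversion with per-complex failure accounting
#'
#' Runs the xyz-to-SMILES pipeline over a manifest of inputs, producing a
#' two-column result (id, SMILES or FAILED:stage) plus counts by failure
#' stage. Processing order is deterministic (manifest order); unreadable
#' rows are counted as FAILED:input and the run continues. When \code{out}
#' exists and \code{resume} is TRUE, ids already present are skipped and
#' results appended.
#'
#' @param manifest a data.frame with columns \code{id}, \code{path} (xyz
#'   file) and \code{charge}, or a path to a TSV file with those columns,
#'   or a directory (every *.xyz inside is converted with charge 0 unless a
#'   \code{charges.tsv} with columns id/charge sits alongside).
#' @param config pipeline configuration.
#' @param out optional path of the TSV to write.
#' @param resume skip ids already present in \code{out}.
#' @return a list (the run report): \code{results} data.frame with columns
#'   \code{id}, \code{status}, \code{smiles}; \code{counts} table of
#'   statuses; \code{config} snapshot; \code{version}.
#' @export
runBatch <- function(manifest, config = tmcConfig(), out = NULL,
                     resume = FALSE) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (dir.exists(manifest)) {
      files <- sort(list.files(manifest, pattern = "\\.xyz$",
                               full.names = TRUE))
      ids <- sub("\\.xyz$", "", basename(files))
      charges <- rep(0L, length(files))
      chFile <- file.path(manifest, "charges.tsv")
      if (file.exists(chFile)) {
        ch <- utils::read.delim(chFile, stringsAsFactors = FALSE)
        charges <- ch$charge[match(ids, ch$id)]
        charges[is.na(charges)] <- 0L
      }
      manifest <- data.frame(id = ids, path = files, charge = charges,
                             stringsAsFactors = FALSE)
    } else {
      manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    }
  }
  stopifnot(all(c("id", "path", "charge") %in% names(manifest)))

  done <- character(0)
  if (resume && !is.null(out) && file.exists(out)) {
    prev <- utils::read.delim(out, header = FALSE,
                              col.names = c("id", "result"),
                              stringsAsFactors = FALSE)
    done <- prev$id
  }

  rows <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    id <- as.character(manifest$id[k])
    if (id %in% done) next
    res <- tryCatch({
      q <- suppressWarnings(as.integer(manifest$charge[k]))
      if (is.na(q)) stop("bad charge")
      xyzToSmiles(manifest$path[k], q, config)
    }, error = function(e) list(ok = FALSE, stage = "input",
                                message = conditionMessage(e)))
    if (!isTRUE(res$ok) && identical(res$stage, "parse")) res$stage <- "input"
    if (isTRUE(res$ok)) {
      rows[[k]] <- data.frame(id = id, status = "OK", smiles = res$smiles,
                              stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- data.frame(id = id,
                              status = paste0("FAILED:", res$stage),
                              smiles = NA_character_,
                              stringsAsFactors = FALSE)
    }
    .tmcLog("batch_item", id = id, status = rows[[k]]$status,
            config = config)
  }
  results <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                              list(data.frame(id = character(),
                                              status = character(),
                                              smiles = character()))))
  if (!is.null(out)) {
    lines <- paste(results$id,
                   ifelse(results$status == "OK", results$smiles,
                          results$status), sep = "\t")
    if (resume && file.exists(out)) cat(lines, file = out, sep = "\n",
                                        append = TRUE)
    else writeLines(lines, out)
  }
  list(results = results,
       counts = table(results$status),
       config = config,
       version = as.character(utils::packageVersion("tmcSMILES")))
}
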