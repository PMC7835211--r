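#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Keeps simulate/permutation functions deterministic without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Structured log line: stage, elapsed seconds, record count.
log_stage <- function(stage, t0, records = NA_integer_, extra = "") {
  elapsed <- as.numeric(proc.time()["elapsed"]) - t0
  message(sprintf("[%s] elapsed=%.2fs records=%s%s", stage, elapsed,
                  ifelse(is.na(records), "-", as.character(records)),
                  if (nzchar(extra)) paste0(" ", extra) else ""))
  invisible(NULL)
}

stage_clock <- function() as.numeric(proc.time()["elapsed"])

# Gene symbols are matched case-insensitively throughout (HGNC convention):
# every identifier is upper-cased on ingestion.
normalize_gene_ids <- function(x) toupper(trimws(as.character(x)))
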