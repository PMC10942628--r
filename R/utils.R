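# Internal helpers shared across modules.

# Chromosome vocabulary (mouse): autosomes 1-19, X, Y, MT.
.chromVocabulary <- function() c(as.character(1:19), "X", "Y", "MT")

# Deterministic substream seed for a (block, unit) pair, derived from one
# master seed. Constants are distinct large primes; result stays < 2^31-1 so
# it is a valid R integer seed on every platform.
.substreamSeed <- function(seed, block, unit = 0L) {
  s <- (as.double(seed) * 48271 + as.double(block) * 104729 +
          as.double(unit) * 7919) %% 2147483629
  as.integer(s)
}

# Run expr with a locally seeded, fully specified RNG; restore global state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Structured format error carrying file / line / field context.
.formatError <- function(file, msg, line = NA, field = NA) {
  loc <- paste0("[file: ", file,
                if (!is.na(line)) paste0(", line: ", line) else "",
                if (!is.na(field)) paste0(", field: ", field) else "", "] ")
  stop(paste0(loc, msg), call. = FALSE)
}

.assayOrStop <- function(sce, name) {
  if (!name %in% SummarizedExperiment::assayNames(sce))
    stop("assay '", name, "' not found; ",
         if (name == "logcounts") "run logNormalizeCounts() first"
         else "supply a count matrix", call. = FALSE)
  SummarizedExperiment::assay(sce, name)
}

.colDataOrStop <- function(sce, name, hint) {
  cd <- SummarizedExperiment::colData(sce)
  if (!name %in% colnames(cd)) stop("column '", name, "' missing from colData; ",
                                    hint, call. = FALSE)
  cd[[name]]
}
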