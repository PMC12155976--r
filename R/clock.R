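# Five-CpG linear DNAm-age clock: representation, I/O, evaluation.

# gene symbol -> formula site key
.SITE_ALIASES <- c(
  ELOVL2   = "methC7-ELOVL2",
  C1orf132 = "methC1-C1orf132",
  MIR29B2C = "methC1-C1orf132",
  TRIM59   = "methC7-TRIM59",
  KLF14    = "methC1-KLF14",
  FHL2     = "methC2-FHL2"
)

# canonical gene column names used in cohort data frames
.CLOCK_GENES <- c("ELOVL2", "C1orf132", "TRIM59", "KLF14", "FHL2")

.clock_cache <- new.env(parent = emptyenv())

#' Read a clock definition file
#'
#' Clock files are JSON with an `intercept` and a `sites` array of
#' `{key, gene, coefficient}` records. Coefficients are stored as decimal
#' strings and parsed on load, so the printed constants are carried verbatim
#' and round-trip through [write_clock()] bit-identically.
#'
#' @param path Path to a clock JSON file.
#' @return An object of class `epi_clock`: a list with `name`, `intercept`
#'   (numeric), `intercept_chr`, and `sites`, a data frame with columns
#'   `site_key`, `gene`, `coefficient`, `coefficient_chr`.
#' @export
read_clock <- function(path) {
  if (!file.exists(path)) stop("clock file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$intercept) || is.null(raw$sites))
    stop("clock file must contain 'intercept' and 'sites'")
  sites <- data.frame(
    site_key = as.character(raw$sites$key),
    gene = as.character(raw$sites$gene),
    coefficient = as.numeric(raw$sites$coefficient),
    coefficient_chr = as.character(raw$sites$coefficient),
    stringsAsFactors = FALSE
  )
  clock <- structure(
    list(
      name = if (is.null(raw$name)) "clock" else raw$name,
      intercept = as.numeric(raw$intercept),
      intercept_chr = as.character(raw$intercept),
      sites = sites
    ),
    class = "epi_clock"
  )
  validate_clock(clock)
  clock
}

#' Write a clock definition file
#'
#' Coefficients are written from their stored decimal strings, so
#' `read_clock(write_clock(clock))` reproduces the clock exactly.
#'
#' @param clock An `epi_clock` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  validate_clock(clock)
  out <- list(
    name = clock$name,
    intercept = clock$intercept_chr,
    sites = lapply(seq_len(nrow(clock$sites)), function(i) {
      list(
        key = clock$sites$site_key[i],
        gene = clock$sites$gene[i],
        coefficient = clock$sites$coefficient_chr[i]
      )
    })
  )
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @keywords internal
validate_clock <- function(clock) {
  if (!inherits(clock, "epi_clock")) stop("not an epi_clock object")
  if (anyDuplicated(clock$sites$site_key))
    stop("duplicate site keys in clock")
  if (!all(is.finite(clock$sites$coefficient)) || !is.finite(clock$intercept))
    stop("clock coefficients must be finite")
  invisible(clock)
}

#' The built-in five-CpG DNAm-age clock
#'
#' Returns the linear blood clock over five CpG sites in ELOVL2,
#' C1orf132/MIR29B2C, TRIM59, KLF14 and FHL2, with methylation expressed in
#' percentage points (0-100). DNAm age in years is the intercept plus the
#' coefficient-weighted sum of the five methylation values. The constants are
#' loaded from a packaged definition file where they are stored as decimal
#' strings, never retyped in code.
#'
#' @return An `epi_clock` object with exactly five sites.
#' @examples
#' clock <- default_clock()
#' compute_dnam_age(c(ELOVL2 = 50, C1orf132 = 30, TRIM59 = 40,
#'                    KLF14 = 5, FHL2 = 35), clock)
#' @export
default_clock <- function() {
  if (is.null(.clock_cache$default)) {
    path <- system.file("extdata", "clock_5cpg.json", package = "epiaccel")
    clock <- read_clock(path)
    if (nrow(clock$sites) != 5L) stop("default clock must have exactly 5 sites")
    .clock_cache$default <- clock
  }
  .clock_cache$default
}

#' @export
print.epi_clock <- function(x, ...) {
  cat("<epi_clock> ", x$name, "\n", sep = "")
  cat("  DNAm age (years) = ", x$intercept_chr, "\n", sep = "")
  for (i in seq_len(nrow(x$sites))) {
    cat(sprintf("    %+s x %s  [%s]\n", x$sites$coefficient_chr[i],
                x$sites$site_key[i], x$sites$gene[i]))
  }
  invisible(x)
}

# Resolve a named methylation vector (site keys or gene aliases) to the
# clock's site order; errors name the first missing site.
.resolve_profile <- function(profile, clock, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(" (", context, ")")
  nm <- names(profile)
  if (is.null(nm)) stop("methylation profile must be a named vector", ctx)
  alias_hit <- nm %in% names(.SITE_ALIASES)
  nm[alias_hit] <- .SITE_ALIASES[nm[alias_hit]]
  idx <- match(clock$sites$site_key, nm)
  if (anyNA(idx)) {
    missing_key <- clock$sites$site_key[which(is.na(idx))[1]]
    stop("profile is missing clock site '", missing_key, "'", ctx)
  }
  vals <- as.numeric(profile[idx])
  if (anyNA(vals)) {
    bad <- clock$sites$site_key[which(is.na(vals))[1]]
    stop("methylation value for '", bad, "' is missing (NA)", ctx)
  }
  if (any(vals < 0 | vals > 100)) {
    i <- which(vals < 0 | vals > 100)[1]
    stop("methylation for '", clock$sites$site_key[i], "' is ", vals[i],
         "; values must lie in [0, 100] percentage points", ctx)
  }
  vals
}

#' Compute DNAm age for one methylation profile
#'
#' Evaluates the affine clock: intercept plus the coefficient-weighted sum of
#' the five site methylation values (percentage points). Names may be either
#' formula site keys (`methC7-ELOVL2`, ...) or gene symbols (`ELOVL2`, ...).
#' Values outside \[0, 100\] are hard errors, not clamped.
#'
#' @param profile Named numeric vector of methylation percentages covering
#'   every clock site.
#' @param clock An `epi_clock`; defaults to [default_clock()].
#' @return DNAm age in years (length-1 numeric).
#' @export
compute_dnam_age <- function(profile, clock = default_clock()) {
  validate_clock(clock)
  vals <- .resolve_profile(profile, clock)
  clock$intercept + sum(clock$sites$coefficient * vals)
}

#' Compute DNAm ages for every observation of a cohort
#'
#' Row-wise [compute_dnam_age()] over a long-format cohort data frame that
#' carries one methylation column per clock gene (`ELOVL2`, `C1orf132`,
#' `TRIM59`, `KLF14`, `FHL2`). Errors gain row context.
#'
#' @param data Data frame with one methylation column per clock gene.
#' @param clock An `epi_clock`.
#' @return Numeric vector of DNAm ages, one per row of `data`.
#' @export
batch_dnam_age <- function(data, clock = default_clock()) {
  validate_clock(clock)
  genes <- clock$sites$gene
  missing_cols <- setdiff(genes, names(data))
  if (length(missing_cols) > 0)
    stop("data is missing methylation column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(data[, genes, drop = FALSE])
  if (anyNA(m) || any(m < 0 | m > 100)) {
    bad <- which(is.na(m) | m < 0 | m > 100, arr.ind = TRUE)[1, ]
    stop("methylation for '", genes[bad[2]], "' out of [0, 100] (row ",
         bad[1], ")")
  }
  as.numeric(clock$intercept + m %*% clock$sites$coefficient)
}
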