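# Internal helpers: chromosome-label normalization, deterministic text
# writing, sub-stream seed derivation.

# "1", "chr1", "Chr1" -> 1L; anything not mapping to an autosome -> NA
normalizeChromosome <- function(x) {
    x <- sub("^[Cc][Hh][Rr]", "", trimws(as.character(x)))
    v <- suppressWarnings(as.integer(x))
    v[!is.na(v) & (v < 1L | v > 22L)] <- NA_integer_
    # reject non-integer strings that as.integer truncated (e.g. "1.5")
    frac <- suppressWarnings(as.numeric(x))
    v[!is.na(v) & !is.na(frac) & frac != v] <- NA_integer_
    v
}

# tokens meaning "missing" in delimited input (case-insensitive)
.missingTokens <- c("", "na", "nan")

parseNumericTokens <- function(x, what = "value") {
    x <- trimws(as.character(x))
    miss <- is.na(x) | tolower(x) %in% .missingTokens
    v <- suppressWarnings(as.numeric(x))
    bad <- !miss & is.na(v)
    if (any(bad))
        stop(sprintf("non-numeric %s token(s): %s", what,
                     paste(utils::head(unique(x[bad]), 5), collapse = ", ")),
             call. = FALSE)
    v[miss] <- NA_real_
    v
}

# %.17g round-trips doubles exactly through text; NA -> "NA"
formatExact <- function(x, digits = 17L) {
    out <- sprintf(paste0("%.", digits, "g"), x)
    out[is.na(x)] <- "NA"
    out
}

# deterministic writer: LF line endings, no quoting, fixed column order
writeDelimExact <- function(cols, file, sep = "\t") {
    stopifnot(length(unique(vapply(cols, length, 1L))) <= 1L)
    header <- paste(names(cols), collapse = sep)
    cols <- lapply(cols, function(x) {
        if (is.double(x)) formatExact(x)
        else { x <- as.character(x); x[is.na(x)] <- "NA"; x }
    })
    body <- if (length(cols) && length(cols[[1]]))
        do.call(paste, c(cols, sep = sep)) else character()
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(c(header, body), con, sep = "\n")
    invisible(NULL)
}

# One RNG sub-stream per (component, index), derived from a single cohort
# seed so that adding samples never perturbs earlier samples' draws.
# Kept inside 32-bit integer range.
substreamSeed <- function(seed, component, index = 0L) {
    s <- (as.numeric(seed) %% 1000003) * 8191 +
        component * 131071 + as.numeric(index)
    as.integer(s %% 2147483629)
}

withSubstream <- function(seed, component, index, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    set.seed(substreamSeed(seed, component, index))
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    expr
}

segLabel <- function(chromosome, q) sprintf("chr%d_%d", chromosome, q)

# parse "chr{c}_{q}" -> data.frame(chromosome, q); NA rows for malformed
parseSegLabel <- function(labels) {
    m <- regmatches(labels, regexec("^chr([0-9]+)_([0-9]+)$", labels))
    chr <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[2]) else NA_integer_, 1L)
    q <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[3]) else NA_integer_, 1L)
    data.frame(label = labels, chromosome = chr, q = q)
}
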