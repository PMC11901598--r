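# internal helpers shared across modules

# half-up rounding (round() is banker's; report tables use commercial rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# percentage of a count over a denominator; denominator <= 0 => undefined (NA)
pct_of <- function(count, denominator, digits = 2) {
  if (length(denominator) != 1 || is.na(denominator) || denominator <= 0) {
    return(rep(NA_real_, length(count)))
  }
  round_half_up(100 * count / denominator, digits)
}

ps_input_error <- function(msg) {
  abort(msg, class = "ps_input_error")
}

# Parse VCF GT strings into canonical unordered diploid calls.
# Phase separators | and / are equivalent; half-calls ("0/.") and ploidy != 2
# become MISSING with one warning naming how many were converted.
parse_gt <- function(gt) {
  gt <- as.character(gt)
  gt[is.na(gt) | gt == "."] <- "./."
  parts <- strsplit(gt, "[/|]", perl = FALSE)
  len <- lengths(parts)
  flat <- suppressWarnings(as.integer(unlist(parts)))
  ok2 <- len == 2L
  a1 <- rep(NA_integer_, length(gt))
  a2 <- rep(NA_integer_, length(gt))
  if (any(ok2)) {
    idx <- cumsum(len)
    first <- idx - 1L
    a1[ok2] <- flat[first[ok2]]
    a2[ok2] <- flat[idx[ok2]]
  }
  half <- ok2 & (is.na(a1) != is.na(a2))
  bad_ploidy <- !ok2
  if (any(half) || any(bad_ploidy)) {
    warn(sprintf(
      "%d half-call and %d non-diploid genotype(s) converted to MISSING",
      sum(half), sum(bad_ploidy)
    ))
  }
  miss <- half | bad_ploidy | is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  list(a1 = lo, a2 = hi)
}

format_gt <- function(a1, a2) {
  out <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
  out[is.na(a1) | is.na(a2)] <- "./."
  out
}

# split a comma-separated ALT string into a character vector ("" => none)
split_alt <- function(alt) {
  ifelse(alt == "" | is.na(alt), list(character(0)), strsplit(alt, ",", fixed = TRUE))
}

write_lines_plain <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

provenance_lines <- function(seed = NULL, config = NULL, prefix = "# ") {
  lines <- paste0(prefix, "polyshare v", as.character(packageVersion("polyshare")))
  if (!is.null(seed)) lines <- c(lines, paste0(prefix, "seed=", seed))
  if (!is.null(config)) lines <- c(lines, paste0(prefix, "config_hash=", hash(config)))
  lines
}
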