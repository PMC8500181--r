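# Shared fixtures, generated in code and memoized for the test run.

.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, config) {
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateExperiment(config)
  .cohortCache[[key]]
}

# Small labeled cohort with a clear injected relaxation signature.
signalCohort <- function() {
  cachedCohort("signal", synthConfig(
    nParticipants = 5, seed = 401,
    bandResponse = c(alpha_h = 0.5, beta_h = -0.5), labelNoiseSd = 0,
    segmentDropout = 0))
}

# Small cohort with no relaxation signal at all.
nullCohort <- function() {
  cachedCohort("null", synthConfig(
    nParticipants = 5, seed = 402, bandResponse = c(),
    asymmetryResponse = 0, labelNoiseSd = 0, segmentDropout = 0))
}

cachedTable <- function(key, builder) {
  if (is.null(.cohortCache[[key]])) .cohortCache[[key]] <- builder()
  .cohortCache[[key]]
}

signalFragmentTable <- function() {
  cachedTable("signalFrag", function() {
    e <- signalCohort()
    suppressMessages(buildFeatureTable(e$recordings, e$labels,
                                       level = "fragment"))
  })
}

# Hand-built section-level FeatureTable from a features x rows matrix.
manualSectionTable <- function(values, segments, sections, participants,
                               featureNames = rownames(values)) {
  colnames(values) <- paste(segments, sections, sep = ".")
  cd <- S4Vectors::DataFrame(segment_id = segments, section = sections,
                             participant_id = participants,
                             row.names = colnames(values))
  rd <- S4Vectors::DataFrame(name = featureNames, row.names = featureNames)
  new("FeatureTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values), rowData = rd, colData = cd,
    metadata = list(level = "section")))
}

# Hand-built fragment-level FeatureTable from a design matrix.
manualFragmentTable <- function(X, participants, y,
                                segments = paste0(participants, "_s1")) {
  rn <- paste0("f", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cd <- S4Vectors::DataFrame(segment_id = segments,
                             participant_id = participants,
                             fragment_index = seq_len(nrow(X)),
                             r_state = y, row.names = rn)
  rd <- S4Vectors::DataFrame(name = colnames(X), row.names = colnames(X))
  m <- t(X)
  colnames(m) <- rn
  new("FeatureTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m), rowData = rd, colData = cd,
    metadata = list(level = "fragment")))
}

# Periodogram power fraction inside [fLo, fHi] - the independent spectral
# oracle used against generated signals.
periodogramBandFraction <- function(x, fs, fLo, fHi) {
  n <- length(x)
  p <- (abs(stats::fft(x))^2)[seq_len(floor(n / 2))]
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(p[f >= fLo & f <= fHi]) / sum(p)
}
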