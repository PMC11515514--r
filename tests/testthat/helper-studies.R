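# Lazily computed, cached desk-scale studies shared by the acceptance
# tests (meta-training runs are expensive; several criteria read different
# aspects of the same study).

.studyCache <- new.env(parent = emptyenv())

sinusoidStudy <- function(nSeeds = 5L) {
    key <- sprintf("sin%d", nSeeds)
    if (is.null(.studyCache[[key]]))
        .studyCache[[key]] <- lapply(seq_len(nSeeds), function(s)
            runSinusoidExperiment(seed = s, nEvalTasks = 30L))
    .studyCache[[key]]
}

calibrationStudy <- function(nSeeds = 5L) {
    key <- sprintf("cal%d", nSeeds)
    if (is.null(.studyCache[[key]]))
        .studyCache[[key]] <- lapply(seq_len(nSeeds), function(s)
            runCalibrationExperiment(seed = s))
    .studyCache[[key]]
}
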