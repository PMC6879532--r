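## package-local cache for filter designs (keyed by name + sampling rate)
.filter_cache_env <- new.env(parent = emptyenv())

.cached_filter <- function(name, fs, design) {
    key <- paste0(name, "@", fs)
    if (is.null(.filter_cache_env[[key]]))
        .filter_cache_env[[key]] <- design()
    .filter_cache_env[[key]]
}
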