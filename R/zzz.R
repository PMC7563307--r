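#' @keywords internal
"_PACKAGE"

## data.table non-standard evaluation is used inside this package
.datatable.aware <- TRUE
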