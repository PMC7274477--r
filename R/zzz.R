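# Required so data.table's [ dispatch works from this package's namespace
# without importing the whole data.table API.
.datatable.aware <- TRUE
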