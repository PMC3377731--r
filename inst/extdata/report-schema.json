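{
  "required": ["meta", "sd_table", "auc_table", "sig_table", "retention"],
  "table_columns": {
    "sd_table": ["method", "platform", "mean", "sd"],
    "auc_table": ["method", "platform", "subset", "mean", "sd"],
    "sig_table": ["method", "platform", "mean", "sd"],
    "retention": ["species", "array_retained", "qpcr_retained", "common"]
  }
}
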