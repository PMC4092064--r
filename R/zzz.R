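utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "N", "m", "contig", "pos", "class", "count",
  "gene_id", "read_id", "frag_start", "frag_end", "origin_strand", "length",
  "start", "end", "strand", "percent", "meth", "unmeth", "seed_idx", "p", "e",
  "score", "mm1", "mm2", "reason", "status", "insert", "region_id",
  "mean_percent", "n_sites", "no_data", "offset", "gene", "gmean", "n_genes",
  "mean_meth", "cpg_percent", "site", "animal", "pa", "pb", "p_adj",
  "indistinguishable", "expr_class", "cpg_class", "base", "gbase", "cpg_c",
  "cpg_g", "mate", "pair", "top", "r", "bin_low", "bin_high"))
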