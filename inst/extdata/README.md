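# Bundled data files

Both files are **synthetic stand-ins**, generated by code: per-region
lists of deregulated feature identifiers whose overlap structure embeds
a known reference pattern used by the tests and the acceptance script —
five proteins (Mapt, Map2, Map1b, Map1a, Sgip1) present in all four
region lists, and two miRNAs (miR-128-3p shared by hippocampus and
olfactory bulb; let-7i-5p shared by neocortex and olfactory bulb). All
other member names are synthetic fillers chosen to reach the per-region
totals (39/53/127/115 PTM proteins; 8/7/11/1 miRNAs).

- `synthetic_ptm_protein_sets.tsv` — columns `region`, `feature_id`
- `synthetic_mirna_sets.tsv` — columns `region`, `feature_id`
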