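# Example run configuration: the nasal arrangement with corrected currents
# on a coarsened phantom. All omitted keys take their documented defaults
# (see ?load_config); the resolved defaults are embedded in the report
# provenance.
schema_version: 1
montage: B+E_corrected
phases: [same, anti]
grid_resolution_deg: 1
phantom:
  element_size: 8
  seed: 1
output_dir: ocufield_out
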