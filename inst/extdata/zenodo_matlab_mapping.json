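{
  "comment": "Field mapping for the deposited virtual-population MATLAB container. All knowledge of the container layout lives here so that layout drift requires editing only this file. Paths are '/'-separated struct field chains into the loaded MATLAB object; {i} is the subject index placeholder.",
  "subjects_array": "data",
  "fields": {
    "age": "age",
    "height": "height",
    "rho": "rho"
  },
  "geometry": {
    "aortic_segments": "aorta/segments",
    "segment_length": "L",
    "segment_r_in": "Rin",
    "segment_r_out": "Rout",
    "k1": "k1",
    "k2": "k2",
    "k3": "k3",
    "h_over_r": 0.15
  },
  "path_lengths": {
    "ao": "paths/ao", "cf": "paths/cf", "ba": "paths/ba",
    "cb": "paths/cb", "cr": "paths/cr", "ft": "paths/ft", "ha": "paths/ha"
  },
  "fs": "fs",
  "pressure_unit": "mmHg",
  "waves": {
    "aortic_root.pressure": "P/AorticRoot",
    "aortic_root.flow_velocity": "U/AorticRoot",
    "desc_aorta.flow_velocity": "U/DescAorta",
    "carotid.pressure": "P/Carotid",
    "carotid.area": "A/Carotid",
    "brachial.pressure": "P/Brachial",
    "radial.pressure": "P/Radial",
    "femoral.pressure": "P/Femoral",
    "ankle.pressure": "P/AntTibial",
    "digital.ppg": "PPG/Digital",
    "ankle.ppg": "PPG/AntTibial"
  }
}
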