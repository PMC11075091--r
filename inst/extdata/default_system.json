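{
  "geometry": {
    "d_source_samplemask_cm": 69,
    "d_samplemask_sample_cm": 3,
    "d_source_detmask_cm": 84,
    "d_source_detector_cm": 86,
    "effective_energy_kev": 18,
    "sample_magnification": null
  },
  "sample_mask": [
    { "id": "slit20", "shape": "slit", "aperture_um": 20, "period_um": 79, "band_height_cm": 1, "septa_transmission": 0 },
    { "id": "slit10", "shape": "slit", "aperture_um": 10, "period_um": 79, "band_height_cm": 1, "septa_transmission": 0 },
    { "id": "slit5",  "shape": "slit", "aperture_um": 5,  "period_um": 79, "band_height_cm": 1, "septa_transmission": 0 },
    { "id": "circ10", "shape": "circle", "aperture_um": 10, "period_um": 79, "band_height_cm": 1, "septa_transmission": 0 }
  ],
  "detector": {
    "pixel_pitch_um": 50,
    "n_cols": 2400,
    "n_rows": 2400,
    "detmask_aperture_um": 17,
    "detmask_period_um": 98,
    "line_skipping": true,
    "effective_pixel_height_um": 40
  },
  "source": {
    "horizontal_fwhm_um": 70,
    "vertical_fwhm_um": 100
  },
  "acquisition": {
    "i0_rate": 10000,
    "working_fraction": 0.5,
    "flank": "positive",
    "flat_cadence": 100,
    "n_darks": 1,
    "overhead_per_step_s": 0,
    "back_and_forth_span_periods": 10
  }
}
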