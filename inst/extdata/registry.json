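{
  "version": "1",
  "abstract": {
    "negFB": {
      "params": {
        "k_act": 1,
        "k_deg": 0.5,
        "k_inh": 0.5,
        "k_ab": 0.2,
        "k_db": 0.1
      },
      "D_A": 2,
      "D_B": 2,
      "rest": {
        "A": 0,
        "B": 0
      },
      "point_amplitude": 1,
      "sequence_amplitude": 1,
      "sequence_width": 0.3,
      "tuned": {
        "interval": 3,
        "spacing": 4
      }
    },
    "negFF": {
      "params": {
        "k_act": 10,
        "k_deg": 1,
        "k_inh": 40,
        "k_b": 4,
        "k_db": 0.02
      },
      "D_A": 0.5,
      "D_B": 0.5,
      "rest": {
        "A": 0,
        "B": 0
      },
      "point_amplitude": 10,
      "sequence_amplitude": 10,
      "sequence_width": 0.3,
      "tuned": {
        "interval": 2.5,
        "spacing": 4
      }
    },
    "FHN": {
      "params": {
        "k_a": 10,
        "k_t": 0.67,
        "a": 1,
        "b": 0.8,
        "offset_A": 0,
        "offset_B": 0.7
      },
      "D_A": 1,
      "D_B": 1,
      "rest": {
        "A": -1.19940803524403,
        "B": -0.624260044055044
      },
      "point_amplitude": 0.4,
      "sequence_amplitude": 0.4,
      "sequence_width": 0.3,
      "tuned": {
        "interval": 2,
        "spacing": 2
      }
    },
    "switch": {
      "params": {
        "k1a": 0.9,
        "k2a": 9,
        "k2b": 0.36,
        "k4a": 6,
        "k4b": 0.8,
        "k3a": 0.23,
        "k3b": 0.03
      },
      "D_A": 5,
      "D_B": 5,
      "rest": {
        "A": 0,
        "B": 0
      },
      "point_amplitude": 1,
      "sequence_amplitude": 1,
      "sequence_width": 0.3,
      "tuned": {
        "interval": 2,
        "spacing": 4
      }
    }
  },
  "mapk_rates": {
    "k_ca_pump": 7,
    "cam_kf": 1,
    "cam_kb": 2,
    "kf_raf": 0.15,
    "k_raf_off": 0.4,
    "kcat_pkc_raf": 0.5,
    "kcat_mek": 6,
    "kcat_pp2a": 0.8,
    "kcat_mapk": 6,
    "kcat_mkp": 0.9,
    "kcat_pkc": 2,
    "k_pkc_off": 1,
    "kcat_phos": 0.1,
    "k_phos_off": 0.004,
    "kcat_fbm": 5,
    "kcat_fb": 5,
    "Km": 0.1
  },
  "mapk_species": [
    {
      "name": "Ca",
      "rest": 0.08,
      "D": 20
    },
    {
      "name": "CaM",
      "rest": 10,
      "D": 4
    },
    {
      "name": "CaMCa",
      "rest": 0,
      "D": 4
    },
    {
      "name": "Raf",
      "rest": 0.5,
      "D": 0
    },
    {
      "name": "Raf_a",
      "rest": 0,
      "D": 0
    },
    {
      "name": "MEK",
      "rest": 0.8,
      "D": 1
    },
    {
      "name": "MEK_p",
      "rest": 0,
      "D": 1
    },
    {
      "name": "MAPK",
      "rest": 1.2,
      "D": 1
    },
    {
      "name": "MAPK_p",
      "rest": 0,
      "D": 1
    },
    {
      "name": "MAPK_pp",
      "rest": 0,
      "D": 1
    },
    {
      "name": "PKC",
      "rest": 0.5,
      "D": 1
    },
    {
      "name": "PKC_a",
      "rest": 0,
      "D": 0
    },
    {
      "name": "Phos",
      "rest": 0.5,
      "D": 3
    },
    {
      "name": "Phos_a",
      "rest": 0,
      "D": 3
    },
    {
      "name": "MKP",
      "rest": 1,
      "D": 1
    },
    {
      "name": "PP2A",
      "rest": 1,
      "D": 1
    }
  ],
  "geometry": {
    "dend_length_um": 60,
    "dend_diam_um": 1,
    "n_spines": 49,
    "n_stim": 5,
    "stim_spacing_um": 3,
    "seed": 20170419
  }
}
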