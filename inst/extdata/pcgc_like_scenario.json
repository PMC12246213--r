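{
  "nodes": ["CHRMdGV", "CILIAdGV", "LVO", "HLHS", "HTX", "ECA", "STAT45", "MORT", "ARREST", "VENT7"],
  "parents": {
    "CHRMdGV": [],
    "CILIAdGV": [],
    "LVO": "CHRMdGV",
    "HLHS": ["CHRMdGV", "LVO"],
    "HTX": "CILIAdGV",
    "ECA": ["CHRMdGV", "CILIAdGV"],
    "STAT45": ["HTX", "LVO"],
    "MORT": ["CHRMdGV", "CILIAdGV", "STAT45"],
    "ARREST": ["CHRMdGV", "CILIAdGV", "STAT45"],
    "VENT7": ["CHRMdGV", "CILIAdGV", "STAT45"]
  },
  "cpts": {
    "CHRMdGV": 0.056,
    "CILIAdGV": 0.053,
    "LVO": [0.276780902299759, 0.462347980470484],
    "HLHS": [0, 0, 0.410408447241637, 0.493135061967802],
    "HTX": [0.0883363259406325, 0.255645805592543],
    "ECA": [0.28, 0.5, 0.4, 0.6],
    "STAT45": [0.15, 0.3, 0.35, 0.45],
    "MORT": [0.0371665645424702, 0.0646760242884149, 0.0509393322118163, 0.0886429382947779, 0.0817664419934346, 0.142287253434513, 0.112066530865996, 0.195014464248511],
    "ARREST": [0.0462019317396249, 0.0762797908864407, 0.0680407413654921, 0.112335855400324, 0.0924038634792498, 0.152559581772881, 0.136081482730984, 0.224671710800648],
    "VENT7": [0.121057124506999, 0.189035364443962, 0.166909085396777, 0.260634968123367, 0.217902824112599, 0.340263655999132, 0.300436353714199, 0.46914294262206]
  },
  "N": null,
  "smoothing": {
    "policy": "none",
    "value": 0
  },
  "roles": {
    "CHRMdGV": "genotype",
    "CILIAdGV": "genotype",
    "LVO": "cardiac_phenotype",
    "HLHS": "cardiac_phenotype",
    "HTX": "cardiac_phenotype",
    "ECA": "extracardiac",
    "STAT45": "surgical",
    "MORT": "outcome",
    "ARREST": "outcome",
    "VENT7": "outcome"
  },
  "anchors": {
    "dgv_union": 0.106032,
    "p_lvo": 0.287172658677319,
    "p_hlhs": 0.12,
    "p_htx": 0.0972037283621838,
    "p_mort": 0.05,
    "p_arrest": 0.06,
    "p_vent": 0.15,
    "abs_lvo_chrm": 1.61,
    "abs_hlhs_chrm": 1.9,
    "abs_htx_cilia": 2.63,
    "rel_mort_chrm": 1.8,
    "rel_arrest_chrm": 1.7,
    "rel_vent_chrm": 1.6,
    "rel_mort_cilia": 1.4,
    "rel_arrest_cilia": 1.5,
    "rel_vent_cilia": 1.4
  }
}
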