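# Default label vocabulary for colposcopy annotation sets.
# Mask classes fall into three categories; tags into four.  The attribute
# map lists, per class, the legal values of each clinical attribute.
masks:
  - name: Cervix
    category: physiological-anatomical
  - name: Squamous epithelium
    category: physiological-anatomical
    attributes:
      epithelium type: [original, metaplastic]
  - name: External os
    category: physiological-anatomical
  - name: Columnar epithelium
    category: physiological-anatomical
  - name: nSCJ
    category: physiological-anatomical
  - name: Transformation zone
    category: physiological-anatomical
  - name: Acetowhite epithelium
    category: findings
  - name: Erythroplakia
    category: findings
  - name: Iodine-negative zone
    category: findings
  - name: Rimmed glandular openings
    category: findings
  - name: Endometriosis
    category: findings
  - name: Mosaicism
    category: findings
  - name: Polyp
    category: findings
  - name: Punctation
    category: findings
  - name: Atypical vessels
    category: findings
  - name: Inflammatory changes
    category: findings
  - name: Atrophy
    category: findings
  - name: Exophytic changes
    category: findings
  - name: Glandular ectopy
    category: findings
  - name: Irregular surface
    category: findings
  - name: Papilloma
    category: findings
  - name: Leukoplakia
    category: findings
  - name: Erosion
    category: findings
  - name: Decidual changes (in pregnancy)
    category: findings
  - name: Condyloma
    category: findings
  - name: Mucus
    category: obstacles-artifacts
  - name: Blood
    category: obstacles-artifacts
  - name: Medical instruments
    category: obstacles-artifacts
tags:
  procedural stage:
    - Stage 0 - before rinsing
    - Stage 1 - after saline application
    - Stage 2 - after application of acetic acid
    - Stage 3 - after application of Lugol's solution
  clinical assessment:
    - Normal colposcopic findings
    - Abnormal colposcopic findings
  image quality:
    - High quality image
    - Low quality image
    - Unusable image
  technical:
    - Green filter
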