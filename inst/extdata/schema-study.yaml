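# Full study schema: the six core columns plus follow-up dates and the
# derived calculations (windowed blood-pressure mean, last weight before
# the event, diabetes history).  Items deliberately appear out of
# dependency order -- CHF_AFTER_DATE is declared before STARTDATE, which
# it depends on -- to exercise the engine's execution ordering.
content_model: CIM-RDF
items:
  - name: SEX
    elements:
      - element: "SDTM:DM.DMSEX"
    derivation:
      fn: VALUE
  - name: BIRTH_DATE
    elements:
      - element: "SDTM:DM.BRTHDTC"
    derivation:
      fn: VALUE
  - name: ACS_DATE
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10051592"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: FIRST_DATE
  - name: MI_DATE
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10000891"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: FIRST_DATE
  - name: UA_DATE
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10002388"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: FIRST_DATE
  - name: CHF_BEFORE_ACS
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10007559"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: EXISTS_BEFORE
      index: ACS_DATE
  - name: CHF_AFTER_ACS
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10007559"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: EXISTS_AFTER
      index: STARTDATE
  - name: CHF_AFTER_DATE
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10007559"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: FIRST_DATE
      index: STARTDATE
  - name: STARTDATE
    derivation:
      fn: DATE_OFFSET
      index: ACS_DATE
      offset_days: 30
  - name: DEATH_DATE
    elements:
      - element: "SDTM:DM.DTHDTC"
    derivation:
      fn: VALUE
  - name: TRANSFER_DATE
    elements:
      - element: "SDTM:DM.RFPENDTC"
    derivation:
      fn: VALUE
  - name: LASTDATE
    derivation:
      fn: MIN_DATE
      candidates: [DEATH_DATE, TRANSFER_DATE]
      constants: ["2011-12-31"]
  - name: T2D_BEFORE_ACS
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10067585"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: EXISTS_BEFORE
      index: ACS_DATE
  - name: T2D_FIRST_DATE
    elements:
      - element: "SDTM:MH.MHPTCD"
        value: "10067585"
      - element: "SDTM:MH.MHSTDTC"
    derivation:
      fn: FIRST_DATE
  - name: SBP_MEAN_1Y_BEFORE_ACS
    elements:
      - element: "SDTM:VS.SYSBP"
      - element: "SDTM:VS.VSDTC"
    derivation:
      fn: MEAN_IN_WINDOW
      index: ACS_DATE
      window_days: 365
  - name: LAST_WEIGHT_BEFORE_ACS
    elements:
      - element: "SDTM:VS.WEIGHT"
      - element: "SDTM:VS.VSDTC"
    derivation:
      fn: LAST_VALUE_BEFORE
      index: ACS_DATE
  - name: HBA1C_MEAN_1Y_BEFORE_ACS
    elements:
      - element: "SDTM:LB.HBA1C"
      - element: "SDTM:LB.LBDTC"
    derivation:
      fn: MEAN_IN_WINDOW
      index: ACS_DATE
      window_days: 365
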