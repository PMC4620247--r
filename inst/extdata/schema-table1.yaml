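# Core data collection set schema: the six study columns, annotated with
# SDTM data elements and MedDRA value bindings.  Medical-history items
# pair the problem code with the start date of the SAME entry; existence
# flags are computed relative to the ACS index ("before" = strictly
# before the event date, "after" = on or after the stabilized start,
# event date + 30 days).
content_model: CIM-RDF
items:
  - name: SEX
    elements:
      - element: "SDTM:DM.DMSEX"
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
      index: ACS_DATE
      index_offset_days: 30
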