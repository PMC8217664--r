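{
  "schema_version": "1.0",
  "macro": {
    "SAMPLE": "S1",
    "TARGETBP": "1760000",
    "VCFDIR": null
  },
  "workflow": [
    {
      "name": "align",
      "command": "cat <qc.clean> > /dev/null; echo bam > [bam]",
      "from": [
        {
          "from": "qc",
          "frompid": "clean",
          "topid": "clean"
        }
      ],
      "to": [
        {
          "to": "pindel",
          "topid": "bam",
          "frompid": "bam"
        },
        {
          "to": "strelka2",
          "topid": "bam",
          "frompid": "bam"
        },
        {
          "to": "vardict",
          "topid": "bam",
          "frompid": "bam"
        },
        {
          "to": "varscan2",
          "topid": "bam",
          "frompid": "bam"
        }
      ]
    },
    {
      "name": "merge",
      "command": "Rscript -e '.libPaths(NULL); invisible(quit(status=dagcall::cli_dispatch(commandArgs(TRUE))))' merge --caller strelka2=<strelka2.vcf> --caller vardict=<vardict.vcf> --caller varscan2=<varscan2.vcf> --caller pindel=<pindel.vcf> --min-callers 2 --min-vaf 0.01 --sample #SAMPLE# --out [merged] --table [candidates]",
      "from": [
        {
          "from": "strelka2",
          "frompid": "vcf",
          "topid": "v1"
        },
        {
          "from": "vardict",
          "frompid": "vcf",
          "topid": "v2"
        },
        {
          "from": "varscan2",
          "frompid": "vcf",
          "topid": "v3"
        },
        {
          "from": "pindel",
          "frompid": "vcf",
          "topid": "v4"
        }
      ],
      "to": [
        {
          "to": "report",
          "topid": "merged",
          "frompid": "merged"
        }
      ]
    },
    {
      "name": "pindel",
      "command": "cat <align.bam> > /dev/null; cp #VCFDIR#/pindel.vcf [vcf]",
      "from": [
        {
          "from": "align",
          "frompid": "bam",
          "topid": "bam"
        }
      ],
      "to": [
        {
          "to": "merge",
          "topid": "v4",
          "frompid": "vcf"
        }
      ]
    },
    {
      "name": "qc",
      "command": "cat <fq> > /dev/null; echo clean > [clean]",
      "from": [],
      "to": [
        {
          "to": "align",
          "topid": "clean",
          "frompid": "clean"
        }
      ]
    },
    {
      "name": "report",
      "command": "Rscript -e '.libPaths(NULL); invisible(quit(status=dagcall::cli_dispatch(commandArgs(TRUE))))' maf --in <merge.merged> --sample #SAMPLE# --popfreq-threshold 0.01 --target-bp #TARGETBP# --out [results]",
      "from": [
        {
          "from": "merge",
          "frompid": "merged",
          "topid": "merged"
        }
      ],
      "to": []
    },
    {
      "name": "strelka2",
      "command": "cat <align.bam> > /dev/null; cp #VCFDIR#/strelka2.vcf [vcf]",
      "from": [
        {
          "from": "align",
          "frompid": "bam",
          "topid": "bam"
        }
      ],
      "to": [
        {
          "to": "merge",
          "topid": "v1",
          "frompid": "vcf"
        }
      ]
    },
    {
      "name": "vardict",
      "command": "cat <align.bam> > /dev/null; cp #VCFDIR#/vardict.vcf [vcf]",
      "from": [
        {
          "from": "align",
          "frompid": "bam",
          "topid": "bam"
        }
      ],
      "to": [
        {
          "to": "merge",
          "topid": "v2",
          "frompid": "vcf"
        }
      ]
    },
    {
      "name": "varscan2",
      "command": "cat <align.bam> > /dev/null; cp #VCFDIR#/varscan2.vcf [vcf]",
      "from": [
        {
          "from": "align",
          "frompid": "bam",
          "topid": "bam"
        }
      ],
      "to": [
        {
          "to": "merge",
          "topid": "v3",
          "frompid": "vcf"
        }
      ]
    }
  ]
}
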